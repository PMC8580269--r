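#' IGX2: heterogeneity of the gene-exposure estimates
#'
#' The I-squared statistic of the gene-exposure estimates across SNPs,
#' measuring the variability in instrument strength that governs the
#' regression-dilution attenuation of MR-Egger:
#' \deqn{Q_{GX} = \sum_j v_j (\hat\gamma_j - \bar\gamma_w)^2, \qquad
#'       I^2_{GX} = \max\!\left(0, \frac{Q_{GX} - (J-1)}{Q_{GX}}\right),}
#' with \eqn{v_j = 1/se(\hat\gamma_j)^2} and \eqn{\bar\gamma_w} the
#' v-weighted mean.  Values of at least 0.9 are conventionally required
#' for MR-Egger.
#'
#' @param s An `mr_summary_set` with at least 2 SNPs.
#' @return IGX2 in [0, 1].
#' @export
igx2 <- function(s) {
  stopifnot(inherits(s, "mr_summary_set"))
  j <- length(s$gx_beta)
  if (j < 2L) stop("igx2 requires at least 2 SNPs", call. = FALSE)
  v <- 1 / s$gx_se^2
  gm <- sum(v * s$gx_beta) / sum(v)
  q <- sum(v * (s$gx_beta - gm)^2)
  if (q <= 0) return(0)
  max(0, (q - (j - 1)) / q)
}

#' Cochran's Q heterogeneity statistic of the Wald ratios
#'
#' \eqn{Q = \sum_j w_j (\hat\beta_j - \hat\beta_{pooled})^2}; under
#' homogeneity and well-estimated SEs, Q is approximately chi-squared with
#' J-1 df when the pooled value is the IVW estimate.
#'
#' @param r An `mr_ratio_set` with at least 2 SNPs.
#' @param pooled The pooled causal estimate (typically IVW).
#' @return Q (non-negative).
#' @export
cochran_q <- function(r, pooled) {
  stopifnot(inherits(r, "mr_ratio_set"))
  if (length(r$ratios) < 2L) stop("Q requires at least 2 SNPs", call. = FALSE)
  sum(r$weights * (r$ratios - pooled)^2)
}

# joint OLS of one or more responses on all genotype columns (intercept
# included) against a single factorization of the centered normal
# equations; Y is an n x m matrix of responses.  Avoids materializing the
# model matrix at biobank N.
joint_genotype_fit <- function(g, Y) {
  storage.mode(g) <- "double"
  Y <- as.matrix(Y)
  n <- nrow(g)
  gm <- colMeans(g)
  ym <- colMeans(Y)
  xtx <- crossprod(g) - n * tcrossprod(gm)
  xty <- crossprod(g, Y) - n * outer(gm, ym)
  coef <- solve(xtx, xty)
  fitted <- g %*% coef
  fitted <- sweep(fitted, 2, colMeans(fitted) - ym)
  resid <- Y - fitted
  tss <- colSums(sweep(Y, 2, ym)^2)
  list(coef = coef, fitted = fitted, resid = resid,
       r2 = 1 - colSums(resid^2) / tss)
}

#' Variance of a phenotype jointly explained by all instruments
#'
#' R-squared of the joint OLS of the exposure or outcome on all genotype
#' columns.  The calibration targets of the default scenario are 2.3\% for
#' the exposure and (at causal effect 1, no pleiotropy) 0.2\% for the
#' outcome.  By default the adjusted R-squared is returned: with J
#' predictors the raw R-squared is inflated by about J/N even under null
#' effects, which is material for variance fractions as small as 0.2\% at
#' J = 100 (about 0.03 percentage points at N = 300,000).
#'
#' @param cohort An `mr_cohort`.
#' @param target `"exposure"` or `"outcome"`.
#' @param adjusted Remove the J/N overfit inflation (default TRUE).
#' @return R-squared (adjusted values can be slightly negative under null
#'   effects).
#' @export
variance_explained <- function(cohort, target = c("exposure", "outcome"),
                               adjusted = TRUE) {
  stopifnot(inherits(cohort, "mr_cohort"))
  target <- match.arg(target)
  y <- if (target == "exposure") cohort$exposure else cohort$outcome
  r2 <- unname(joint_genotype_fit(cohort$genotypes, y)$r2)
  if (adjusted) {
    n <- length(y)
    j <- ncol(cohort$genotypes)
    r2 <- 1 - (1 - r2) * (n - 1) / (n - j - 1)
  }
  r2
}

#' Decompose the correlation between gene-exposure and gene-outcome errors
#'
#' In a one-sample analysis the estimation errors of the per-SNP
#' gene-exposure and gene-outcome estimates are correlated both through the
#' causal effect and through confounding; only the latter component
#' ("residual correlation") threatens two-sample methods.  This function
#' estimates both from individual-level data:
#' \itemize{
#'   \item `observed`: correlation between the per-individual residuals of
#'     X and of Y after removing the genetic contribution of all
#'     instruments from each (the quantity that drives the correlation of
#'     the two estimate sets);
#'   \item `residual`: the same after first subtracting the causal
#'     contribution `beta_hat * X` from Y, leaving the component
#'     attributable to confounding.
#' }
#' `beta_hat` is typically plugged in from IVW.
#'
#' @param cohort A one-sample `mr_cohort`.
#' @param beta_hat Plug-in causal-effect estimate.
#' @return List with elements `observed` and `residual`, both in [-1, 1].
#' @export
residual_correlation <- function(cohort, beta_hat) {
  stopifnot(inherits(cohort, "mr_cohort"))
  if (cohort$scenario$design == "two_sample")
    stop("residual correlation is defined for shared (one-sample) data",
         call. = FALSE)
  g <- cohort$genotypes
  x <- cohort$exposure; y <- cohort$outcome
  fit <- joint_genotype_fit(g, cbind(x = x, y = y, yb = y - beta_hat * x))
  list(observed = stats::cor(fit$resid[, "x"], fit$resid[, "y"]),
       residual = stats::cor(fit$resid[, "x"], fit$resid[, "yb"]))
}

#' Full instrument-diagnostics report for one replicate
#'
#' Collects the monitored diagnostics: mean per-SNP F, fraction of weak
#' instruments (F < 10), variance explained in exposure and outcome, IGX2,
#' Cochran's Q of the Wald ratios about the IVW estimate, and (one-sample
#' designs only) the residual-correlation decomposition.
#'
#' @param design An `mr_design_sample` (or a single `mr_cohort`, treated as
#'   one-sample).
#' @param full Compute the joint-regression quantities (variance explained,
#'   residual correlation)?  These dominate the cost at large N; set
#'   `FALSE` for estimator-only runs.
#' @return A one-row `data.frame` (class amended with `mr_diagnostics`).
#' @export
mr_diagnostics <- function(design, full = TRUE) {
  if (inherits(design, "mr_cohort"))
    design <- structure(list(cohort_x = design, cohort_y = design,
                             shared = TRUE), class = "mr_design_sample")
  stopifnot(inherits(design, "mr_design_sample"))
  s <- marginal_regressions(design)
  f <- (s$gx_beta / s$gx_se)^2
  r <- wald_ratios(s)
  pooled <- mr_ivw_fe(r)$estimate
  out <- data.frame(
    mean_f = mean(f),
    frac_weak = mean(f < 10),
    r2_exposure = NA_real_,
    r2_outcome = NA_real_,
    igx2 = igx2(s),
    q_stat = cochran_q(r, pooled),
    residual_correlation = NA_real_,
    observed_pair_correlation = NA_real_
  )
  if (full) {
    if (design$shared) {
      # one factorization serves R^2 and the residual-correlation pieces
      cx <- design$cohort_x
      fit <- joint_genotype_fit(cx$genotypes,
                                cbind(x = cx$exposure, y = cx$outcome,
                                      yb = cx$outcome - pooled * cx$exposure))
      adj <- function(r2) 1 - (1 - r2) * (nrow(cx$genotypes) - 1) /
        (nrow(cx$genotypes) - ncol(cx$genotypes) - 1)
      out$r2_exposure <- adj(unname(fit$r2["x"]))
      out$r2_outcome <- adj(unname(fit$r2["y"]))
      out$residual_correlation <- stats::cor(fit$resid[, "x"],
                                             fit$resid[, "yb"])
      out$observed_pair_correlation <- stats::cor(fit$resid[, "x"],
                                                  fit$resid[, "y"])
    } else {
      out$r2_exposure <- variance_explained(design$cohort_x, "exposure")
      out$r2_outcome <- variance_explained(design$cohort_y, "outcome")
    }
  }
  class(out) <- c("mr_diagnostics", class(out))
  out
}
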