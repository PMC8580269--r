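#' Construct a causal-effect estimate
#'
#' Container for one method's estimate: point estimate, SE, 95\% CI,
#' two-sided p-value, and (for MR-Egger) the intercept.  Inference uses a
#' normal reference distribution when `df` is `NA`, otherwise Student t.
#'
#' @param method Method label, one of `"IVW_FE"`, `"IVW_MRE"`, `"WMEDIAN"`,
#'   `"WMODE"`, `"EGGER"`, `"TSLS"`, `"OLS"`.
#' @param estimate Point estimate of the causal effect.
#' @param se Standard error (positive, or NA when unavailable).
#' @param df Degrees of freedom for t inference; NA for normal.
#' @param intercept,intercept_se MR-Egger intercept and its SE.
#' @param n_snps Number of instruments used.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, estimate, se, df = NA_real_,
                        intercept = NA_real_, intercept_se = NA_real_,
                        n_snps = NA_integer_) {
  method <- match.arg(method, c("IVW_FE", "IVW_MRE", "WMEDIAN", "WMODE",
                                "EGGER", "TSLS", "OLS"))
  if (is.finite(se) && se < 0)
    stop("se must be non-negative", call. = FALSE)
  crit <- if (is.na(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  if (is.finite(se) && se > 0) {
    z <- estimate / se
    p <- if (is.na(df)) 2 * stats::pnorm(-abs(z))
         else 2 * stats::pt(-abs(z), df)
    ci <- estimate + c(-1, 1) * crit * se
  } else {
    p <- NA_real_
    ci <- c(estimate, estimate)
  }
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = ci[1], ci_high = ci[2], p_value = p, df = df,
                 intercept = intercept, intercept_se = intercept_se,
                 n_snps = n_snps),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%-7s estimate %8.4f  se %.4f  95%% CI [%.4f, %.4f]  p %.3g\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$p_value))
  if (is.finite(x$intercept))
    cat(sprintf("        intercept %.5f  se %.5f\n", x$intercept,
                x$intercept_se))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             intercept = x$intercept, intercept_se = x$intercept_se,
             n_snps = x$n_snps)
}

#' Per-SNP Wald ratios
#'
#' The SNP-specific causal-effect estimates: gene-outcome estimate divided
#' by gene-exposure estimate, with first-order delta-method SE
#' `gy_se / |gx_beta|` (the "simple" weighting conventional in IVW; the
#' second-order term is omitted).  SNPs with a gene-exposure estimate of
#' exactly zero are excluded with a warning.  The originating summary
#' columns are carried along for the parametric bootstrap of the median and
#' mode estimators.
#'
#' @param s An `mr_summary_set`.
#' @return An object of class `mr_ratio_set`: `ratios`, `ratio_se`,
#'   `weights` (inverse-variance) plus the summary columns.
#' @export
wald_ratios <- function(s) {
  stopifnot(inherits(s, "mr_summary_set"))
  keep <- s$gx_beta != 0
  if (!all(keep))
    warning(sprintf("excluding %d SNP(s) with zero gene-exposure estimate",
                    sum(!keep)), call. = FALSE)
  if (!any(keep)) stop("no usable SNPs", call. = FALSE)
  ratios <- s$gy_beta[keep] / s$gx_beta[keep]
  ratio_se <- s$gy_se[keep] / abs(s$gx_beta[keep])
  structure(list(ratios = ratios, ratio_se = ratio_se,
                 weights = 1 / ratio_se^2,
                 gx_beta = s$gx_beta[keep], gx_se = s$gx_se[keep],
                 gy_beta = s$gy_beta[keep], gy_se = s$gy_se[keep],
                 snp_id = s$snp_id[keep]),
            class = "mr_ratio_set")
}

#' Inverse-variance-weighted fixed-effect estimator
#'
#' Pools the Wald ratios by fixed-effect meta-analysis:
#' \eqn{\hat\beta = \sum w_j \hat\beta_j / \sum w_j} with
#' \eqn{w_j = 1/se_j^2}, \eqn{se = 1/\sqrt{\sum w_j}}; normal inference.
#'
#' @param r An `mr_ratio_set`.
#' @return An `mr_estimate` with method `"IVW_FE"`.
#' @export
mr_ivw_fe <- function(r) {
  stopifnot(inherits(r, "mr_ratio_set"))
  w <- r$weights
  est <- sum(w * r$ratios) / sum(w)
  mr_estimate("IVW_FE", est, sqrt(1 / sum(w)), n_snps = length(w))
}

#' Inverse-variance-weighted multiplicative random-effects estimator
#'
#' Identical point estimate to [mr_ivw_fe()]; the SE is inflated by the
#' square root of the multiplicative overdispersion
#' \eqn{\phi = Q/(J-1)} floored at 1, with Q the Cochran heterogeneity
#' statistic of the ratios about the pooled estimate.
#'
#' @param r An `mr_ratio_set` with at least 2 SNPs.
#' @return An `mr_estimate` with method `"IVW_MRE"`.
#' @export
mr_ivw_mre <- function(r) {
  stopifnot(inherits(r, "mr_ratio_set"))
  j <- length(r$ratios)
  if (j < 2L) stop("IVW_MRE requires at least 2 SNPs", call. = FALSE)
  fe <- mr_ivw_fe(r)
  q <- sum(r$weights * (r$ratios - fe$estimate)^2)
  phi <- max(1, q / (j - 1))
  mr_estimate("IVW_MRE", fe$estimate, fe$se * sqrt(phi), n_snps = j)
}

# weighted median of values b with weights w: sort, form normalized
# cumulative weights at midpoints, linearly interpolate at 0.5
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap over (gx, gy) draws; f maps (ratios, weights) -> point
bootstrap_ratio_se <- function(r, n_boot, f) {
  j <- length(r$ratios)
  est <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    gx <- stats::rnorm(j, r$gx_beta, r$gx_se)
    gy <- stats::rnorm(j, r$gy_beta, r$gy_se)
    ok <- gx != 0
    ratios <- gy[ok] / gx[ok]
    w <- (abs(gx[ok]) / r$gy_se[ok])^2
    est[b] <- f(ratios, w)
  }
  stats::sd(est)
}

#' Weighted median estimator
#'
#' The inverse-variance-weighted median of the Wald ratios: sorts the
#' ratios, forms normalized cumulative weights at the midpoints
#' \eqn{s_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k} and linearly
#' interpolates the sorted ratios at \eqn{s = 0.5}.  Consistent when at
#' least half the weight comes from valid instruments.  The SE comes from a
#' parametric bootstrap: gene-exposure and gene-outcome estimates are
#' resampled from normal distributions centred on their observed values and
#' the estimator recomputed.
#'
#' @param r An `mr_ratio_set` with at least 3 SNPs.
#' @param n_boot Bootstrap draws for the SE (default 1000; a warning is
#'   issued below 100).  `n_boot = 0` skips the bootstrap (SE is NA).
#' @return An `mr_estimate` with method `"WMEDIAN"`.
#' @export
mr_weighted_median <- function(r, n_boot = 1000L) {
  stopifnot(inherits(r, "mr_ratio_set"))
  j <- length(r$ratios)
  if (j < 3L) stop("weighted median requires at least 3 SNPs", call. = FALSE)
  if (n_boot > 0L && n_boot < 100L)
    warning("n_boot below 100; bootstrap SE will be unstable", call. = FALSE)
  est <- weighted_median_point(r$ratios, r$weights)
  se <- if (n_boot > 0L)
    bootstrap_ratio_se(r, n_boot, weighted_median_point) else NA_real_
  mr_estimate("WMEDIAN", est, se, n_snps = j)
}

# mode of the weighted gaussian kernel density over ratios
weighted_mode_point <- function(b, w, bandwidth_factor = 1) {
  if (length(unique(b)) == 1L) return(b[1])
  s0 <- min(stats::sd(b), stats::mad(b))
  h <- bandwidth_factor * 0.9 * s0 * length(b)^(-1 / 5)
  if (h <= 0) return(weighted_median_point(b, w))  # mad 0: fall back
  dens <- function(x)
    vapply(x, function(xx) sum(w * stats::dnorm((xx - b) / h)), 0)
  # density derivative (up to a positive constant): its root at the grid
  # argmax localizes the mode to machine precision, which pure
  # function-value optimization cannot
  ddens <- function(x) sum(w * (b - x) * stats::dnorm((x - b) / h))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512L)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (ddens(lo) > 0 && ddens(hi) < 0)
    stats::uniroot(ddens, c(lo, hi), tol = 1e-14)$root
  else
    stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
}

#' Weighted mode estimator
#'
#' The mode of the inverse-variance-weighted Gaussian kernel density of the
#' Wald ratios; consistent when the largest group of SNPs with the same
#' causal estimate are valid instruments (ZEMPA).  Bandwidth is
#' `bandwidth_factor` times the modified Silverman rule
#' \eqn{0.9\,\min(sd, mad)\,J^{-1/5}} on the ratio spread.  If all ratios
#' coincide the common ratio is returned.  SE by the same parametric
#' bootstrap as [mr_weighted_median()].
#'
#' @param r An `mr_ratio_set` with at least 3 SNPs.
#' @param bandwidth_factor Multiplier on the Silverman bandwidth
#'   (default 1).
#' @param n_boot Bootstrap draws for the SE; 0 skips.
#' @return An `mr_estimate` with method `"WMODE"`.
#' @export
mr_weighted_mode <- function(r, bandwidth_factor = 1, n_boot = 1000L) {
  stopifnot(inherits(r, "mr_ratio_set"))
  j <- length(r$ratios)
  if (j < 3L) stop("weighted mode requires at least 3 SNPs", call. = FALSE)
  est <- weighted_mode_point(r$ratios, r$weights, bandwidth_factor)
  se <- if (n_boot > 0L)
    bootstrap_ratio_se(r, n_boot, function(b, w)
      weighted_mode_point(b, w, bandwidth_factor)) else NA_real_
  mr_estimate("WMODE", est, se, n_snps = j)
}

#' MR-Egger regression
#'
#' Weighted least squares of the gene-outcome on the gene-exposure
#' estimates with an unconstrained intercept, weights \eqn{1/se(\hat\Gamma_j)^2}.
#' All SNPs are first oriented so the gene-exposure estimate is
#' non-negative (flipping the sign of both coordinates), which the
#' intercept's interpretation requires.  The slope estimates the causal
#' effect; the intercept estimates the average directional pleiotropic
#' effect.  SEs carry a multiplicative overdispersion
#' \eqn{\phi = RSS_w/(J-2)} floored at 1; inference uses t with J-2 df.
#'
#' @param s An `mr_summary_set` with at least 3 SNPs.
#' @return An `mr_estimate` with method `"EGGER"`, including `intercept`
#'   and `intercept_se`.
#' @export
mr_egger <- function(s) {
  stopifnot(inherits(s, "mr_summary_set"))
  j <- length(s$gx_beta)
  if (j < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- sign(s$gx_beta)
  flip[flip == 0] <- 1
  x <- s$gx_beta * flip
  y <- s$gy_beta * flip
  w <- 1 / s$gy_se^2
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) stop("gene-exposure estimates are constant", call. = FALSE)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  inter <- yb - slope * xb
  rss <- sum(w * (y - inter - slope * x)^2)
  phi <- max(1, rss / (j - 2))
  se_slope <- sqrt(phi / sxx)
  se_inter <- sqrt(phi * (1 / sw + xb^2 / sxx))
  mr_estimate("EGGER", slope, se_slope, df = j - 2,
              intercept = inter, intercept_se = se_inter, n_snps = j)
}

#' Two-stage least squares
#'
#' The individual-level instrumental-variable estimator using all J SNPs
#' jointly: first stage regresses X on the genotypes (with intercept),
#' second stage regresses Y on the fitted exposure.  Residuals for the SE
#' are evaluated at the observed exposure (the standard IV variance);
#' inference uses t with N-2 df.  Requires individual-level data on the
#' same individuals, i.e. a one-sample design.
#'
#' @param cohort An `mr_cohort`.
#' @return An `mr_estimate` with method `"TSLS"`.
#' @export
mr_tsls <- function(cohort) {
  stopifnot(inherits(cohort, "mr_cohort"))
  g <- cohort$genotypes
  storage.mode(g) <- "double"
  x <- cohort$exposure; y <- cohort$outcome
  n <- length(x)
  gm <- colMeans(g)
  xtx <- crossprod(g) - n * tcrossprod(gm)   # centered first-stage equations
  qr_xtx <- qr(xtx)
  if (qr_xtx$rank < ncol(g)) {
    bad <- qr_xtx$pivot[(qr_xtx$rank + 1L):ncol(g)]
    stop("first stage is rank deficient; collinear columns: ",
         paste0("snp", bad, collapse = ", "), call. = FALSE)
  }
  sgx <- as.vector(crossprod(g, x)) - n * gm * mean(x)
  coef1 <- solve(qr_xtx, sgx)
  xhat <- as.vector(g %*% coef1)
  xhat <- xhat - mean(xhat) + mean(x)
  sxx <- sum((xhat - mean(xhat))^2)
  slope <- sum((xhat - mean(xhat)) * (y - mean(y))) / sxx
  a <- mean(y) - slope * mean(xhat)
  u <- y - a - slope * x            # residuals at observed exposure
  se <- sqrt(sum(u * u) / (n - 2) / sxx)
  mr_estimate("TSLS", slope, se, df = n - 2, n_snps = ncol(g))
}
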