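#' Construct a per-SNP summary-statistic set
#'
#' The flat table of per-SNP gene-exposure and gene-outcome estimates with
#' standard errors that all two-sample MR estimators consume.  Can be built
#' from simulated cohorts via [marginal_regressions()] or read from a TSV of
#' real harmonized summary statistics via [read_summary_set()].
#'
#' @param gx_beta,gx_se Gene-exposure estimates and SEs (length J).
#' @param gy_beta,gy_se Gene-outcome estimates and SEs (length J).
#' @param snp_id Optional SNP identifiers.
#' @param n_gx,n_gy Sample sizes behind each set of estimates (optional).
#' @return An object of class `mr_summary_set`.
#' @export
summary_set <- function(gx_beta, gx_se, gy_beta, gy_se,
                        snp_id = NULL, n_gx = NA_integer_, n_gy = NA_integer_) {
  j <- length(gx_beta)
  if (j < 1L) stop("summary set must contain at least one SNP", call. = FALSE)
  if (length(gx_se) != j || length(gy_beta) != j || length(gy_se) != j)
    stop("gx_beta, gx_se, gy_beta, gy_se must share length", call. = FALSE)
  if (any(!is.finite(gx_se)) || any(gx_se <= 0) ||
      any(!is.finite(gy_se)) || any(gy_se <= 0))
    stop("all standard errors must be strictly positive", call. = FALSE)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(j))
  structure(list(snp_id = as.character(snp_id),
                 gx_beta = as.numeric(gx_beta), gx_se = as.numeric(gx_se),
                 gy_beta = as.numeric(gy_beta), gy_se = as.numeric(gy_se),
                 n_gx = n_gx, n_gy = n_gy),
            class = "mr_summary_set")
}

#' @export
print.mr_summary_set <- function(x, ...) {
  cat(sprintf("mr_summary_set: %d SNPs (n_gx=%s, n_gy=%s)\n",
              length(x$gx_beta), x$n_gx, x$n_gy))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @export
as.data.frame.mr_summary_set <- function(x, ...) {
  data.frame(snp_id = x$snp_id, gx_beta = x$gx_beta, gx_se = x$gx_se,
             gy_beta = x$gy_beta, gy_se = x$gy_se)
}

# genotype moments reused across responses (the double copy of G and its
# column sums of squares dominate the cost at biobank N)
genotype_moments <- function(g) {
  gd <- g
  storage.mode(gd) <- "double"
  gs <- colSums(gd)
  list(gd = gd, gs = gs, sgg = colSums(gd * gd) - gs^2 / nrow(gd))
}

# per-SNP simple-regression moments of y on each genotype column.
# Returns slope, se (n-2 residual divisor) and the genotype sums of squares;
# monomorphic columns are returned with NA and flagged in `poly`.
snp_marginal_stats <- function(g, y, gm = NULL) {
  n <- length(y)
  if (is.null(gm)) gm <- genotype_moments(g)
  gd <- gm$gd; gs <- gm$gs; sgg <- gm$sgg
  sy <- sum(y)
  syy <- sum(y * y) - sy^2 / n
  sgy <- as.vector(crossprod(gd, y)) - gs * sy / n
  poly <- sgg > 0
  slope <- se <- rep(NA_real_, length(sgg))
  slope[poly] <- sgy[poly] / sgg[poly]
  rss <- pmax(syy - slope[poly]^2 * sgg[poly], 0)
  se[poly] <- sqrt(rss / (n - 2) / sgg[poly])
  list(slope = slope, se = se, sgg = sgg, poly = poly)
}

#' Per-SNP marginal regressions: cohorts to summary statistics
#'
#' Reduces individual-level cohorts to the per-SNP summary statistics of a
#' GWAS: the gene-exposure estimates come from simple linear regressions of
#' X on each SNP alone in `cohort_x`, the gene-outcome estimates from simple
#' regressions of Y on each SNP in `cohort_y` (one-SNP-at-a-time, intercepts
#' fitted but not reported; residual variance uses the unbiased n-2
#' divisor).  Monomorphic SNPs (zero genotype variance in either cohort)
#' are excluded with a warning.
#'
#' @param cohort_x Cohort providing the gene-exposure estimates, or an
#'   `mr_design_sample` (in which case `cohort_y` is taken from it).
#' @param cohort_y Cohort providing the gene-outcome estimates; defaults to
#'   `cohort_x` (one-sample analysis).
#' @return An `mr_summary_set`.
#' @export
marginal_regressions <- function(cohort_x, cohort_y = NULL) {
  if (inherits(cohort_x, "mr_design_sample")) {
    cohort_y <- cohort_x$cohort_y
    cohort_x <- cohort_x$cohort_x
  }
  if (is.null(cohort_y)) cohort_y <- cohort_x
  stopifnot(inherits(cohort_x, "mr_cohort"), inherits(cohort_y, "mr_cohort"))
  if (ncol(cohort_x$genotypes) != ncol(cohort_y$genotypes))
    stop("cohorts must share the same number of SNPs", call. = FALSE)
  shared <- identical(cohort_x$genotypes, cohort_y$genotypes)
  gmx <- genotype_moments(cohort_x$genotypes)
  gx <- snp_marginal_stats(cohort_x$genotypes, cohort_x$exposure, gmx)
  gmy <- if (shared) gmx else genotype_moments(cohort_y$genotypes)
  gy <- snp_marginal_stats(cohort_y$genotypes, cohort_y$outcome, gmy)
  keep <- gx$poly & gy$poly
  if (!all(keep))
    warning(sprintf("excluding %d monomorphic SNP(s): %s",
                    sum(!keep), paste(which(!keep), collapse = ", ")),
            call. = FALSE)
  if (!any(keep))
    stop("no polymorphic SNPs left", call. = FALSE)
  summary_set(gx_beta = gx$slope[keep], gx_se = gx$se[keep],
              gy_beta = gy$slope[keep], gy_se = gy$se[keep],
              snp_id = paste0("snp", which(keep)),
              n_gx = length(cohort_x$exposure),
              n_gy = length(cohort_y$outcome))
}

#' Per-SNP F statistics of the gene-exposure regressions
#'
#' \eqn{F_j = (\hat\gamma_j / se(\hat\gamma_j))^2}, the 1-df regression F of
#' the marginal exposure-on-SNP regression (the square of its t statistic).
#'
#' @param cohort An `mr_cohort`.
#' @return Numeric vector of F statistics (NA for monomorphic SNPs).
#' @export
per_snp_f_stats <- function(cohort) {
  stopifnot(inherits(cohort, "mr_cohort"))
  st <- snp_marginal_stats(cohort$genotypes, cohort$exposure)
  (st$slope / st$se)^2
}

#' Observational (OLS) estimate of the exposure-outcome association
#'
#' Plain regression of Y on X in one cohort.  Under confounding its slope
#' reflects the confounded observational association
#' \eqn{\beta + \rho\sigma_x\sigma_y(1 - R^2_G)/\mathrm{var}(X)}, the
#' benchmark against which the direction of estimator bias is read.
#'
#' @param cohort An `mr_cohort`.
#' @return An `mr_estimate` with method label `"OLS"`.
#' @export
ols_observational <- function(cohort) {
  stopifnot(inherits(cohort, "mr_cohort"))
  x <- cohort$exposure; y <- cohort$outcome
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("exposure has zero variance", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  mr_estimate("OLS", slope, se, df = n - 2L, n_snps = ncol(cohort$genotypes))
}

#' Write a summary set to TSV
#'
#' Columns: snp_id, gx_beta, gx_se, gy_beta, gy_se.
#'
#' @param s An `mr_summary_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_set <- function(s, path) {
  stopifnot(inherits(s, "mr_summary_set"))
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a summary set from TSV
#'
#' Accepts the format written by [write_summary_set()] (and any harmonized
#' summary-statistic table with columns snp_id, gx_beta, gx_se, gy_beta,
#' gy_se).
#'
#' @param path Path to a TSV file.
#' @param n_gx,n_gy Optional sample sizes to attach.
#' @return An `mr_summary_set`.
#' @export
read_summary_set <- function(path, n_gx = NA_integer_, n_gy = NA_integer_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "gx_beta", "gx_se", "gy_beta", "gy_se")
  if (!all(need %in% names(d)))
    stop("summary TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  summary_set(d$gx_beta, d$gx_se, d$gy_beta, d$gy_se, snp_id = d$snp_id,
              n_gx = n_gx, n_gy = n_gy)
}
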