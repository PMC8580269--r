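#' Define a simulation scenario
#'
#' A scenario fixes one condition of the simulation study: cohort size,
#' number of instruments, true causal effect, amount of confounding
#' (the correlation between the exposure and outcome error terms),
#' pleiotropy configuration, the genetic architecture of the instruments,
#' and the sampling design (one-sample or two-sample).
#'
#' @details
#' The genetic architecture is parameterized through the per-SNP variance in
#' the exposure explained by each instrument,
#' \deqn{v_j = s\,(c + E_j^k), \qquad E_j \sim \mathrm{Exp}(1),}
#' where `s = effect_scale`, `c = effect_shift` and `k = effect_spread`.
#' The per-allele gene-exposure coefficient is
#' \eqn{\gamma_j = \sqrt{v_j / (2 p_j (1 - p_j))}} with allele frequency
#' \eqn{p_j \sim U(\mathrm{maf\_range})}.  `effect_spread = 1` is an
#' exponential architecture with a strength floor; `effect_spread = 2`
#' (with `effect_shift = 0`) spreads the draws and raises the heterogeneity
#' of instrument strength (the IGX2 statistic) from about 93\% to about 97\%
#' at the default cohort size, at fixed total variance explained.
#'
#' When `effect_scale`, `sigma_x` or `sigma_y` are `NULL` they are
#' calibrated so that: `var(X) = 1`; the instruments jointly explain
#' `target_r2_exposure` of the exposure variance; and, at a reference causal
#' effect of 1 with no confounding, they explain `target_r2_outcome` of the
#' outcome variance.  See [calibrate_effect_scale()] and
#' [calibrate_sigma_y()].
#'
#' @param n_individuals Cohort size N.
#' @param n_snps Number of independent instruments J.
#' @param causal_effect True causal effect \eqn{\beta} of X on Y
#'   (units of Y per unit of X).
#' @param error_correlation Correlation \eqn{\rho \in [-1, 1]} between the
#'   exposure and outcome error terms; nonzero values represent confounding.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`.
#' @param pleiotropy_fraction Fraction of SNPs with a direct effect on Y.
#'   Defaults to 0 under `"none"` and 0.2 otherwise; must be 0 iff
#'   `pleiotropy == "none"`.
#' @param target_r2_exposure Expected fraction of `var(X)` jointly explained
#'   by the instruments (calibration target for `effect_scale`).
#' @param target_r2_outcome Expected fraction of `var(Y)` explained by the
#'   instruments at causal effect 1 with no pleiotropy (calibration target
#'   for `sigma_y`).
#' @param effect_scale Scale s of the per-SNP explained-variance
#'   distribution; `NULL` calibrates it from `target_r2_exposure`.
#' @param effect_shift Strength floor c (dimensionless). The default solves
#'   for an expected 5\% of instruments with marginal F below 10 at the
#'   default cohort size (see [calibrate_effect_shift()]).
#' @param effect_spread Spread exponent k applied to the exponential draw.
#' @param sigma_x SD of the exposure error; `NULL` sets `var(X) = 1`.
#' @param sigma_y SD of the outcome error; `NULL` calibrates from
#'   `target_r2_outcome`.
#' @param maf_range Length-2 allele-frequency bounds, within (0, 1).
#' @param design `"one_sample"` (gene-exposure and gene-outcome estimates
#'   from the same individuals) or `"two_sample"`.
#' @param seed Master integer seed for the scenario.
#' @return An object of class `mr_scenario` (a validated list of the above
#'   fields plus the calibrated values).
#' @examples
#' sc <- mr_scenario(n_individuals = 5000, n_snps = 20, causal_effect = 1,
#'                   error_correlation = 0.2)
#' sc$sigma_y^2   # approximately 10.5 when var(X) = 1
#' @export
mr_scenario <- function(n_individuals = 300000L,
                        n_snps = 100L,
                        causal_effect = 0,
                        error_correlation = 0,
                        pleiotropy = c("none", "balanced", "directional"),
                        pleiotropy_fraction = NULL,
                        target_r2_exposure = 0.023,
                        target_r2_outcome = 0.002,
                        effect_scale = NULL,
                        effect_shift = 0.1613,
                        effect_spread = 1,
                        sigma_x = NULL,
                        sigma_y = NULL,
                        maf_range = c(0.01, 0.99),
                        design = c("one_sample", "two_sample"),
                        seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  design <- match.arg(design)
  if (is.null(pleiotropy_fraction))
    pleiotropy_fraction <- if (pleiotropy == "none") 0 else 0.2
  if (is.null(sigma_x))
    sigma_x <- sqrt(1 - target_r2_exposure)
  sc <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    causal_effect = causal_effect,
    error_correlation = error_correlation,
    pleiotropy = pleiotropy,
    pleiotropy_fraction = pleiotropy_fraction,
    target_r2_exposure = target_r2_exposure,
    target_r2_outcome = target_r2_outcome,
    effect_scale = effect_scale,
    effect_shift = effect_shift,
    effect_spread = effect_spread,
    sigma_x = sigma_x,
    sigma_y = sigma_y,
    maf_range = as.numeric(maf_range),
    design = design,
    seed = as.integer(seed)
  ), class = "mr_scenario")
  # validate user-supplied fields before calibration needs them
  pre <- sc
  if (is.null(pre$effect_scale)) pre$effect_scale <- 1
  if (is.null(pre$sigma_y)) pre$sigma_y <- 1
  validate_scenario(pre)
  if (is.null(sc$effect_scale))
    sc$effect_scale <- calibrate_effect_scale(target_r2_exposure, sc)
  if (is.null(sc$sigma_y))
    sc$sigma_y <- calibrate_sigma_y(target_r2_outcome, sc)
  validate_scenario(sc)
  sc
}

#' @export
print.mr_scenario <- function(x, ...) {
  cat("mr_scenario:",
      sprintf("N=%d, J=%d, beta=%g, rho=%g, pleiotropy=%s (%.0f%%), %s",
              x$n_individuals, x$n_snps, x$causal_effect,
              x$error_correlation, x$pleiotropy,
              100 * x$pleiotropy_fraction, x$design), "\n")
  cat(sprintf("  effect scale=%.4g shift=%g spread=%g; sigma_x=%.4g sigma_y=%.4g; maf in (%g, %g); seed=%d\n",
              x$effect_scale, x$effect_shift, x$effect_spread,
              x$sigma_x, x$sigma_y, x$maf_range[1], x$maf_range[2], x$seed))
  invisible(x)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "mr_scenario"))
  fail <- function(field, msg)
    stop(sprintf("invalid scenario: field '%s' %s", field, msg), call. = FALSE)
  if (!is.finite(sc$n_individuals) || sc$n_individuals < 2L)
    fail("n_individuals", "must be an integer >= 2")
  if (!is.finite(sc$n_snps) || sc$n_snps < 1L)
    fail("n_snps", "must be an integer >= 1")
  if (!is.finite(sc$causal_effect))
    fail("causal_effect", "must be a finite real")
  if (!is.finite(sc$error_correlation) || abs(sc$error_correlation) > 1)
    fail("error_correlation", "must lie in [-1, 1]")
  if (!sc$pleiotropy %in% c("none", "balanced", "directional"))
    fail("pleiotropy", "must be one of none/balanced/directional")
  if (sc$pleiotropy_fraction < 0 || sc$pleiotropy_fraction > 1)
    fail("pleiotropy_fraction", "must lie in [0, 1]")
  if ((sc$pleiotropy == "none") != (sc$pleiotropy_fraction == 0))
    fail("pleiotropy_fraction", "must be 0 if and only if pleiotropy == 'none'")
  for (f in c("effect_scale", "sigma_x", "sigma_y"))
    if (!is.finite(sc[[f]]) || sc[[f]] <= 0)
      fail(f, "must be strictly positive")
  if (sc$effect_shift < 0) fail("effect_shift", "must be >= 0")
  if (sc$effect_spread <= 0) fail("effect_spread", "must be > 0")
  if (length(sc$maf_range) != 2L || any(!is.finite(sc$maf_range)) ||
      sc$maf_range[1] <= 0 || sc$maf_range[2] >= 1 ||
      sc$maf_range[1] >= sc$maf_range[2])
    fail("maf_range", "must satisfy 0 < lower < upper < 1")
  if (!sc$design %in% c("one_sample", "two_sample"))
    fail("design", "must be one_sample or two_sample")
  invisible(sc)
}

# E[shift + E^spread] for E ~ Exp(1)
effect_family_mean <- function(shift, spread) shift + gamma(spread + 1)

#' Calibrate the effect-scale parameter to a target exposure R-squared
#'
#' Returns the scale s of the per-SNP explained-variance distribution such
#' that the instruments are expected to jointly explain `target_r2` of the
#' exposure variance.  Closed form: the expected genetic variance is
#' \eqn{J\,s\,(c + \Gamma(k + 1))} and the exposure error contributes
#' `sigma_x^2`, so \eqn{s = r^2 \sigma_x^2 / ((1 - r^2)\, J\, (c + \Gamma(k+1)))}.
#'
#' @param target_r2 Target fraction of exposure variance in (0, 1).
#' @param scenario An `mr_scenario` (only J, sigma_x, effect_shift and
#'   effect_spread are used; effect_scale may still be NULL).
#' @return The calibrated positive scale.
#' @export
calibrate_effect_scale <- function(target_r2, scenario) {
  if (!is.finite(target_r2) || target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must lie strictly between 0 and 1", call. = FALSE)
  vg <- target_r2 * scenario$sigma_x^2 / (1 - target_r2)
  vg / (scenario$n_snps *
          effect_family_mean(scenario$effect_shift, scenario$effect_spread))
}

#' Calibrate the outcome error SD to a target outcome R-squared
#'
#' Solves for `sigma_y` so that, at a reference causal effect
#' (`reference_beta`, default 1) with no pleiotropy and no confounding, the
#' instruments explain `target_r2` of the outcome variance:
#' \eqn{\sigma_y^2 = \beta^2 V_g / r^2 - \beta^2 \mathrm{var}(X)} with
#' \eqn{V_g} the expected genetic variance of the exposure.  With the default
#' calibration (`var(X) = 1`, exposure R-squared 2.3\%, outcome R-squared
#' 0.2\%) this gives \eqn{\sigma_y^2 = 10.5}.
#'
#' @param target_r2 Target fraction of outcome variance in (0, 1).
#' @param scenario An `mr_scenario` with effect_scale already set.
#' @param reference_beta Causal effect at which the target is defined.
#' @return The calibrated positive SD.
#' @export
calibrate_sigma_y <- function(target_r2, scenario, reference_beta = 1) {
  if (!is.finite(target_r2) || target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must lie strictly between 0 and 1", call. = FALSE)
  vg <- scenario$effect_scale * scenario$n_snps *
    effect_family_mean(scenario$effect_shift, scenario$effect_spread)
  var_x <- vg + scenario$sigma_x^2
  s2 <- reference_beta^2 * vg / target_r2 - reference_beta^2 * var_x
  if (s2 <= 0)
    stop("target_r2 too large: implied outcome error variance is not positive",
         call. = FALSE)
  sqrt(s2)
}

#' Calibrate the strength floor to a target weak-instrument fraction
#'
#' Solves for the `effect_shift` parameter c such that the expected fraction
#' of instruments with marginal F statistic below `f_threshold` equals
#' `target_weak_frac`, at the scenario's cohort size.  Under the
#' explained-variance architecture the F statistic of SNP j is (to first
#' order) noncentral chi-squared with 1 df and noncentrality
#' \eqn{N v_j}, independent of allele frequency, so the expectation reduces
#' to a one-dimensional integral over the exponential draw.
#'
#' @param target_weak_frac Target fraction in (0, 1), e.g. 0.05.
#' @param scenario An `mr_scenario`; its effect_scale is re-derived from
#'   `target_r2_exposure` at each candidate shift.
#' @param f_threshold Weak-instrument cutoff (default 10).
#' @return The calibrated shift (>= 0).
#' @export
calibrate_effect_shift <- function(target_weak_frac, scenario,
                                   f_threshold = 10) {
  if (!is.finite(target_weak_frac) || target_weak_frac <= 0 ||
      target_weak_frac >= 1)
    stop("target_weak_frac must lie strictly between 0 and 1", call. = FALSE)
  n <- scenario$n_individuals
  k <- scenario$effect_spread
  r2 <- scenario$target_r2_exposure
  j <- scenario$n_snps
  weak <- function(cc) {
    s <- r2 / (j * (cc + gamma(k + 1)))   # vg in units of var(X)=1
    f <- function(e)
      stats::pchisq(f_threshold, df = 1, ncp = n * s * (cc + e^k)) * exp(-e)
    stats::integrate(f, 0, 60, rel.tol = 1e-9)$value
  }
  if (weak(0) < target_weak_frac)
    return(0)
  stats::uniroot(function(cc) weak(cc) - target_weak_frac,
                 interval = c(0, 50), tol = 1e-7)$root
}

scenario_fields <- c(
  "n_individuals", "n_snps", "causal_effect", "error_correlation",
  "pleiotropy", "pleiotropy_fraction", "target_r2_exposure",
  "target_r2_outcome", "effect_scale", "effect_shift", "effect_spread",
  "sigma_x", "sigma_y", "maf_range", "design", "seed")

#' Read a scenario from a JSON file
#'
#' The file must contain exactly the `mr_scenario` fields (missing optional
#' fields fall back to defaults); unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return An `mr_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), scenario_fields)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(mr_scenario, raw)
}

#' Write a scenario to a JSON file
#'
#' @param scenario An `mr_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
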