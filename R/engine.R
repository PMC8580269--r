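#' Deterministic per-replicate seed
#'
#' Derives the seed of replicate `r` from the master seed by a fixed
#' integer recurrence, so any replicate can be reproduced in isolation
#' without replaying the stream.  Values stay below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param replicate Replicate index (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(master_seed, replicate) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(replicate) * 1013904223) %% m)
}

default_methods <- function(design) {
  m <- c("IVW_FE", "IVW_MRE", "WMEDIAN", "WMODE", "EGGER")
  if (design == "one_sample") m <- c(m, "TSLS", "OLS")
  m
}

#' Run one scenario of the simulation study
#'
#' For each replicate: seed the RNG from `(master_seed, replicate)`, draw
#' true effects, simulate the design, reduce to summary statistics, apply
#' every requested estimator, and (optionally) compute the diagnostics
#' report.  A failing estimator is recorded with its error message and the
#' run continues.  The result is fully determined by
#' `(scenario, n_reps, master_seed)`.
#'
#' @param scenario An `mr_scenario`.
#' @param n_reps Number of replicates (the reference study used 1000;
#'   reduced counts widen Monte-Carlo error proportionally).
#' @param methods Character vector of method labels; `NULL` selects all
#'   methods applicable to the design (`TSLS`/`OLS` are one-sample only).
#' @param master_seed Master seed; defaults to `scenario$seed`.
#' @param n_boot Bootstrap draws for the median/mode SEs.
#' @param diagnostics One of `"full"` (includes joint-regression
#'   quantities), `"summary"` (cheap summary-statistic diagnostics only)
#'   or `"none"`.
#' @return An object of class `mr_scenario_result`: the scenario, a
#'   replicate-level `estimates` data frame (replicate, method, estimate,
#'   se, ci_low, ci_high, p_value, error), a `diagnostics` data frame,
#'   and the seeds used.
#' @export
run_scenario <- function(scenario, n_reps, methods = NULL,
                         master_seed = scenario$seed, n_boot = 1000L,
                         diagnostics = c("full", "summary", "none")) {
  validate_scenario(scenario)
  diagnostics <- match.arg(diagnostics)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (is.null(methods)) methods <- default_methods(scenario$design)
  bad <- setdiff(methods, default_methods("one_sample"))
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (scenario$design == "two_sample" &&
      length(intersect(methods, c("TSLS", "OLS"))))
    stop("TSLS and OLS require a one-sample design", call. = FALSE)

  est_rows <- vector("list", n_reps)
  diag_rows <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    set.seed(replicate_seed(master_seed, rep_i))
    design <- simulate_design(scenario)
    s <- marginal_regressions(design)
    r <- wald_ratios(s)
    one <- lapply(methods, function(m) {
      res <- tryCatch({
        e <- switch(m,
          IVW_FE  = mr_ivw_fe(r),
          IVW_MRE = mr_ivw_mre(r),
          WMEDIAN = mr_weighted_median(r, n_boot = n_boot),
          WMODE   = mr_weighted_mode(r, n_boot = n_boot),
          EGGER   = mr_egger(s),
          TSLS    = mr_tsls(design$cohort_x),
          OLS     = ols_observational(design$cohort_x))
        cbind(as.data.frame(e)[c("method", "estimate", "se", "ci_low",
                                 "ci_high", "p_value", "intercept")],
              error = NA_character_)
      }, error = function(cnd) {
        data.frame(method = m, estimate = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, intercept = NA_real_,
                   error = conditionMessage(cnd))
      })
      res
    })
    est_rows[[rep_i]] <- cbind(replicate = rep_i, do.call(rbind, one))
    if (diagnostics != "none")
      diag_rows[[rep_i]] <- cbind(replicate = rep_i,
                                  mr_diagnostics(design,
                                                 full = diagnostics == "full"))
  }
  structure(list(
    scenario = scenario,
    estimates = do.call(rbind, est_rows),
    diagnostics = if (diagnostics != "none") do.call(rbind, diag_rows),
    n_reps = n_reps,
    master_seed = master_seed,
    methods = methods
  ), class = "mr_scenario_result")
}

#' @export
print.mr_scenario_result <- function(x, ...) {
  cat(sprintf("mr_scenario_result: %d replicates x %d methods (seed %d)\n",
              x$n_reps, length(x$methods), x$master_seed))
  print(x$scenario)
  invisible(x)
}

#' Aggregate replicate estimates into performance rows
#'
#' Per method: mean estimate, empirical SE (population SD of the
#' estimates, so that `rmse^2 = bias^2 + empirical_se^2` holds exactly),
#' mean model-based SE, empirical coverage of the method's own 95\% CI,
#' and RMSE about the true effect.  Failed replicates are excluded and
#' counted.
#'
#' @param result An `mr_scenario_result`.
#' @param truth True causal effect; defaults to the scenario's.
#' @return A `data.frame` with one row per method (columns: method, n_used,
#'   n_failed, mean_estimate, empirical_se, mean_model_se, coverage, rmse).
#' @export
performance_metrics <- function(result, truth = NULL) {
  stopifnot(inherits(result, "mr_scenario_result"))
  if (is.null(truth)) truth <- result$scenario$causal_effect
  est <- result$estimates
  out <- lapply(unique(est$method), function(m) {
    d <- est[est$method == m, ]
    ok <- is.finite(d$estimate)
    n_failed <- sum(!ok)
    d <- d[ok, ]
    if (nrow(d) < 2L) {
      warning("fewer than 2 successful replicates for method ", m,
              "; row omitted", call. = FALSE)
      return(NULL)
    }
    mean_est <- mean(d$estimate)
    emp_se <- sqrt(mean((d$estimate - mean_est)^2))
    data.frame(method = m, n_used = nrow(d), n_failed = n_failed,
               mean_estimate = mean_est, empirical_se = emp_se,
               mean_model_se = mean(d$se),
               coverage = mean(d$ci_low <= truth & truth <= d$ci_high),
               rmse = sqrt(mean((d$estimate - truth)^2)))
  })
  do.call(rbind, out)
}

#' Q-Q data for null p-values of one method
#'
#' Pairs the sorted observed p-values of a null scenario with the uniform
#' order-statistic expectations \eqn{(i - 0.5)/n}, both on the
#' \eqn{-\log_{10}} scale.  Only defined for scenarios with a zero causal
#' effect.
#'
#' @param result An `mr_scenario_result` whose scenario has
#'   `causal_effect == 0`.
#' @param method Method label.
#' @return A `data.frame` with columns `expected_neglog10p` and
#'   `observed_neglog10p`, ordered by increasing observed p.
#' @export
qq_data <- function(result, method) {
  stopifnot(inherits(result, "mr_scenario_result"))
  if (result$scenario$causal_effect != 0)
    stop("Q-Q calibration is defined for null scenarios only", call. = FALSE)
  p <- result$estimates$p_value[result$estimates$method == method]
  p <- sort(p[is.finite(p)])
  n <- length(p)
  if (n < 1L) stop("no p-values for method ", method, call. = FALSE)
  data.frame(expected_neglog10p = -log10((seq_len(n) - 0.5) / n),
             observed_neglog10p = -log10(p))
}

#' Trim estimates for plotting
#'
#' Retains estimates within `window` of the true value (default 0.8, the
#' outlier rule used for the boxplot figures).  Used only by the plotting
#' layer; performance metrics always use all replicates.
#'
#' @param estimates Numeric vector of estimates.
#' @param truth True causal effect.
#' @param window Positive half-width of the retained band.
#' @return The retained estimates.
#' @export
trim_for_plotting <- function(estimates, truth, window = 0.8) {
  if (!is.finite(window) && window > 0) return(estimates)
  if (window <= 0) stop("window must be positive", call. = FALSE)
  estimates[is.finite(estimates) & abs(estimates - truth) <= window]
}

#' Run a grid of scenarios
#'
#' Convenience wrapper: runs [run_scenario()] over a list of scenarios
#' (e.g. the factorial of causal effect, confounding, pleiotropy and
#' design) and names the results.
#'
#' @param scenarios List of `mr_scenario` objects.
#' @param n_reps Replicates per scenario.
#' @param ... Passed to [run_scenario()].
#' @return A named list of `mr_scenario_result` objects.
#' @export
run_grid <- function(scenarios, n_reps, ...) {
  out <- lapply(scenarios, run_scenario, n_reps = n_reps, ...)
  names(out) <- vapply(scenarios, function(sc)
    sprintf("beta%g_rho%g_%s_%s", sc$causal_effect, sc$error_correlation,
            sc$pleiotropy, sc$design), "")
  out
}
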