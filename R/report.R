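#' Boxplots of replicate estimates across a scenario grid
#'
#' Renders the study's headline figure layout: one panel per
#' (pleiotropy, design) cell, estimates grouped by confounding level on the
#' x axis and by method within each level, with a horizontal reference line
#' at the true effect.  Estimates further than `trim_window` from the truth
#' are removed from the figure only (never from performance tables).
#'
#' @param results A list of `mr_scenario_result` objects (e.g. from
#'   [run_grid()]); all must share the same causal effect.
#' @param trim_window Trim half-width (default 0.8); `Inf` disables.
#' @param file Optional output path; written as PNG, and additionally as
#'   SVG when `file` ends in `.svg` and the device is available.
#' @return A `ggplot` object, invisibly when `file` is given.
#' @export
render_boxplots <- function(results, trim_window = 0.8, file = NULL) {
  stopifnot(length(results) >= 1L)
  truth <- results[[1]]$scenario$causal_effect
  if (!all(vapply(results, function(r) r$scenario$causal_effect, 0) == truth))
    stop("all results must share the same true causal effect", call. = FALSE)
  dat <- do.call(rbind, lapply(results, function(res) {
    sc <- res$scenario
    d <- res$estimates
    d <- d[is.finite(d$estimate) &
             abs(d$estimate - truth) <= trim_window, ]
    if (!nrow(d)) {
      warning(sprintf("no plottable estimates for scenario rho=%g %s %s",
                      sc$error_correlation, sc$pleiotropy, sc$design),
              call. = FALSE)
      return(NULL)
    }
    data.frame(rho = sc$error_correlation, pleiotropy = sc$pleiotropy,
               design = sc$design, method = d$method, estimate = d$estimate)
  }))
  dat$pleiotropy <- factor(dat$pleiotropy,
                           c("none", "balanced", "directional"))
  dat$design <- factor(dat$design, c("one_sample", "two_sample"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$rho),
                                         y = .data$estimate,
                                         fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.25) +
    ggplot2::geom_hline(yintercept = truth, linetype = "dashed") +
    ggplot2::facet_grid(pleiotropy ~ design) +
    ggplot2::labs(x = "correlation of error terms (confounding)",
                  y = "causal-effect estimate", fill = "method") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 7, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Q-Q plot of null p-values
#'
#' Observed versus expected \eqn{-\log_{10}} p-values for one method under
#' null scenarios, one curve per confounding level.
#'
#' @param results List of null-scenario `mr_scenario_result` objects.
#' @param method Method label.
#' @param file Optional output path (see [render_boxplots()]).
#' @return A `ggplot` object.
#' @export
render_qq <- function(results, method, file = NULL) {
  dat <- do.call(rbind, lapply(results, function(res) {
    q <- qq_data(res, method)
    q$rho <- factor(res$scenario$error_correlation)
    q$design <- res$scenario$design
    q
  }))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected_neglog10p,
                                         y = .data$observed_neglog10p,
                                         colour = .data$rho)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~design) +
    ggplot2::labs(x = expression(-log[10](italic(p)) ~ expected),
                  y = expression(-log[10](italic(p)) ~ observed)) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Render a wide performance table
#'
#' Reshapes per-scenario, per-method performance rows into a wide table
#' (scenarios as rows; method-major, metric-minor columns) rounded to
#' 3 decimals, and optionally writes it as TSV.
#'
#' @param rows A `data.frame` of performance rows with a `scenario` label
#'   column and a `method` column (e.g. [performance_metrics()] output
#'   augmented with a `scenario` column), or a named list of such frames.
#' @param file Optional TSV output path.
#' @param digits Rounding for the formatted table (default 3).
#' @return The wide `data.frame` (numeric, unrounded); written TSV is
#'   rounded to `digits`.
#' @export
render_performance_table <- function(rows, file = NULL, digits = 3) {
  if (is.list(rows) && !is.data.frame(rows))
    rows <- do.call(rbind, Map(function(d, nm) cbind(scenario = nm, d),
                               rows, names(rows)))
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (is.null(rows$scenario)) rows$scenario <- "scenario"
  metrics <- c("mean_estimate", "empirical_se", "mean_model_se",
               "coverage", "rmse")
  metrics <- intersect(metrics, names(rows))
  methods <- unique(rows$method)
  scenarios <- unique(rows$scenario)
  wide <- data.frame(scenario = scenarios)
  for (m in methods) for (met in metrics) {
    col <- paste(m, met, sep = ".")
    wide[[col]] <- vapply(scenarios, function(sc) {
      v <- rows[rows$scenario == sc & rows$method == m, met]
      if (length(v)) v[[1]] else NA_real_
    }, 0)
  }
  if (!is.null(file)) {
    out <- wide
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wide
}
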