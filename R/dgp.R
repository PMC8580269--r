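#' Draw the true per-SNP parameters of a scenario
#'
#' Draws allele frequencies, gene-exposure effects and (where configured)
#' direct pleiotropic effects on the outcome.  Gene-exposure effects follow
#' the explained-variance architecture of the scenario (see
#' [mr_scenario()]); pleiotropic effect magnitudes are drawn independently
#' from the same distribution, so instrument strength is independent of the
#' direct effects (the InSIDE condition).  Which SNPs are pleiotropic is
#' decided by a seeded shuffle of the SNP indices; under balanced
#' pleiotropy the signs are independent fair coin flips, under directional
#' pleiotropy all direct effects are positive.
#'
#' Consumes the current RNG stream; the engine is responsible for seeding.
#'
#' @param scenario An `mr_scenario`.
#' @return An object of class `mr_true_effects`: list with `allele_freqs`,
#'   `gx_effects` (all positive, coded-allele orientation) and
#'   `pleio_effects` (zero for non-pleiotropic SNPs).
#' @export
draw_true_effects <- function(scenario) {
  validate_scenario(scenario)
  j <- scenario$n_snps
  p <- stats::runif(j, scenario$maf_range[1], scenario$maf_range[2])
  tpq <- 2 * p * (1 - p)
  v <- scenario$effect_scale *
    (scenario$effect_shift + stats::rexp(j)^scenario$effect_spread)
  gx <- sqrt(v / tpq)
  alpha <- numeric(j)
  n_pleio <- round(j * scenario$pleiotropy_fraction)
  if (n_pleio > 0L) {
    idx <- sample.int(j)[seq_len(n_pleio)]
    va <- scenario$effect_scale *
      (scenario$effect_shift + stats::rexp(n_pleio)^scenario$effect_spread)
    mag <- sqrt(va / tpq[idx])
    sgn <- switch(scenario$pleiotropy,
                  balanced = sample(c(-1, 1), n_pleio, replace = TRUE),
                  directional = rep(1, n_pleio))
    alpha[idx] <- sgn * mag
  }
  structure(list(allele_freqs = p, gx_effects = gx, pleio_effects = alpha),
            class = "mr_true_effects")
}

#' Simulate one individual-level cohort
#'
#' Generates genotypes \eqn{G_{ij} \sim \mathrm{Binomial}(2, p_j)}
#' independently across SNPs, bivariate-normal error terms with SDs
#' `(sigma_x, sigma_y)` and correlation `error_correlation`, and assembles
#' the phenotypes by the linear structural equations
#' \deqn{X = G\gamma + \epsilon_x, \qquad
#'       Y = \beta X + G\alpha + \epsilon_y.}
#' The error vectors are stored on the cohort so the structural equations
#' hold exactly given the stored draws.
#'
#' @param scenario An `mr_scenario`.
#' @param truth An `mr_true_effects` consistent with the scenario.
#' @return An object of class `mr_cohort`: genotype matrix (numeric
#'   storage, values 0/1/2), `exposure`, `outcome`, stored errors
#'   `eps_x`/`eps_y`, plus `truth` and `scenario`.
#' @export
simulate_cohort <- function(scenario, truth) {
  validate_scenario(scenario)
  stopifnot(inherits(truth, "mr_true_effects"),
            length(truth$gx_effects) == scenario$n_snps)
  n <- scenario$n_individuals
  j <- scenario$n_snps
  # stored as double (values 0/1/2): avoids repeated integer-to-double
  # copies of the N x J matrix in the linear-algebra layers
  g <- matrix(0, n, j)
  for (k in seq_len(j))
    g[, k] <- stats::rbinom(n, 2L, truth$allele_freqs[k])
  rho <- scenario$error_correlation
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  eps_x <- scenario$sigma_x * z1
  eps_y <- scenario$sigma_y * (rho * z1 + sqrt(1 - rho^2) * z2)
  x <- as.vector(g %*% truth$gx_effects) + eps_x
  y <- scenario$causal_effect * x + eps_y
  if (any(truth$pleio_effects != 0))
    y <- y + as.vector(g %*% truth$pleio_effects)
  structure(list(genotypes = g, exposure = x, outcome = y,
                 eps_x = eps_x, eps_y = eps_y,
                 truth = truth, scenario = scenario),
            class = "mr_cohort")
}

#' Simulate one replicate under the scenario's sampling design
#'
#' Under the one-sample design the gene-exposure and gene-outcome cohorts
#' are the same object; under the two-sample design two independent cohorts
#' are drawn under identical conditions (shared true effects), and the
#' gene-exposure estimates are later taken from the first, the gene-outcome
#' estimates from the second.
#'
#' @param scenario An `mr_scenario`.
#' @param truth Optional `mr_true_effects`; drawn from the current RNG
#'   stream when `NULL`.
#' @return An object of class `mr_design_sample`: list with `cohort_x`,
#'   `cohort_y` and logical `shared`.
#' @export
simulate_design <- function(scenario, truth = NULL) {
  validate_scenario(scenario)
  if (is.null(truth)) truth <- draw_true_effects(scenario)
  cohort_x <- simulate_cohort(scenario, truth)
  if (scenario$design == "one_sample") {
    out <- list(cohort_x = cohort_x, cohort_y = cohort_x, shared = TRUE)
  } else {
    out <- list(cohort_x = cohort_x,
                cohort_y = simulate_cohort(scenario, truth),
                shared = FALSE)
  }
  structure(out, class = "mr_design_sample")
}
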