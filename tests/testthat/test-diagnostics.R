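test_that("igx2 matches hand arithmetic and truncates at zero", {
  # homogeneous gene-exposure estimates: Q = 0, truncated to 0
  s0 <- ss(c(1, 1, 1), c(0.1, 0.2, 0.3), c(1, 1, 1), c(1, 1, 1))
  expect_equal(igx2(s0), 0, tolerance = 1e-12)

  # 3-SNP hand computation
  gx <- c(0.1, 0.2, 0.4)
  gxse <- c(0.05, 0.1, 0.08)
  v <- 1 / gxse^2
  gm <- sum(v * gx) / sum(v)
  q <- sum(v * (gx - gm)^2)
  s <- ss(gx, gxse, c(1, 1, 1), c(1, 1, 1))
  expect_equal(igx2(s), max(0, (q - 2) / q), tolerance = 1e-12)
  expect_error(igx2(ss(1, 1, 1, 1)), "at least 2")

  # deep heterogeneity: igx2 approaches 1
  s2 <- ss(c(0.01, 1, 5), c(0.001, 0.001, 0.001), c(1, 1, 1), c(1, 1, 1))
  expect_gt(igx2(s2), 0.99)
})

test_that("Cochran's Q matches hand arithmetic", {
  r <- rs(c(0, 2, 4), c(1, 1, 1))
  expect_equal(cochran_q(r, 2), 8, tolerance = 1e-12)
  expect_equal(cochran_q(rs(c(2, 2), c(1, 3)), 2), 0, tolerance = 1e-12)
})

test_that("variance explained agrees with the joint lm R-squared", {
  sc <- tiny_scenario(n_individuals = 500L, n_snps = 8L, causal_effect = 1)
  set.seed(30)
  ch <- simulate_cohort(sc, draw_true_effects(sc))
  expect_equal(variance_explained(ch, "exposure", adjusted = FALSE),
               summary(lm(ch$exposure ~ ch$genotypes))$r.squared,
               tolerance = 1e-10)
  expect_equal(variance_explained(ch, "outcome", adjusted = FALSE),
               summary(lm(ch$outcome ~ ch$genotypes))$r.squared,
               tolerance = 1e-10)
  expect_equal(variance_explained(ch, "exposure"),
               summary(lm(ch$exposure ~ ch$genotypes))$adj.r.squared,
               tolerance = 1e-10)

  # zero effects: R^2 is pure overfit noise, about J/N
  sc0 <- tiny_scenario(n_individuals = 4000L, n_snps = 5L,
                       effect_scale = 1e-12, sigma_y = 1)
  set.seed(31)
  ch0 <- simulate_cohort(sc0, draw_true_effects(sc0))
  expect_lt(variance_explained(ch0, "exposure"), 0.01)
})

test_that("residual correlation isolates confounding from causal effect", {
  n <- 50000L
  # rho = 0, beta = 1: observed pair correlation positive, residual ~ 0
  sc <- mr_scenario(n_individuals = n, n_snps = 30L, causal_effect = 1,
                    error_correlation = 0)
  set.seed(32)
  ch <- simulate_cohort(sc, draw_true_effects(sc))
  rc <- residual_correlation(ch, beta_hat = 1)
  expect_lt(abs(rc$residual), 0.02)
  expect_gt(rc$observed, 0.2)

  # rho = 0.4, beta = 0: residual ~ rho (mild attenuation), observed ~ rho
  sc2 <- mr_scenario(n_individuals = n, n_snps = 30L, causal_effect = 0,
                     error_correlation = 0.4)
  set.seed(33)
  ch2 <- simulate_cohort(sc2, draw_true_effects(sc2))
  rc2 <- residual_correlation(ch2, beta_hat = 0)
  expect_equal(rc2$residual, 0.4, tolerance = 0.03)

  # fully null model: both components vanish
  sc3 <- mr_scenario(n_individuals = n, n_snps = 30L)
  set.seed(34)
  ch3 <- simulate_cohort(sc3, draw_true_effects(sc3))
  rc3 <- residual_correlation(ch3, beta_hat = 0)
  expect_lt(abs(rc3$residual), 0.02)
  expect_lt(abs(rc3$observed), 0.02)

  sc4 <- mr_scenario(n_individuals = 100L, n_snps = 3L,
                     design = "two_sample")
  set.seed(35)
  ch4 <- simulate_cohort(sc4, draw_true_effects(sc4))
  expect_error(residual_correlation(ch4, 0), "one-sample")
})

test_that("residual correlation is monotone in rho and tracks the
           cross-replicate error-pair correlation oracle", {
  n <- 20000L
  rhos <- c(-0.4, -0.2, 0, 0.2, 0.4)
  set.seed(36)
  vals <- vapply(rhos, function(rho) {
    sc <- mr_scenario(n_individuals = n, n_snps = 40L, causal_effect = 1,
                      error_correlation = rho)
    mean(replicate(3, {
      ch <- simulate_cohort(sc, draw_true_effects(sc))
      residual_correlation(ch, beta_hat = 1)$residual
    }))
  }, 0)
  expect_true(all(diff(vals) > 0))

  # oracle: empirical correlation of the per-SNP estimation-error pairs
  # (gamma_hat - gamma, Gamma_hat - (beta*gamma + alpha)) across replicates
  sc <- mr_scenario(n_individuals = 4000L, n_snps = 50L, causal_effect = 0,
                    error_correlation = 0.4)
  set.seed(37)
  pairs <- replicate(30, {
    ch <- simulate_cohort(sc, draw_true_effects(sc))
    s <- marginal_regressions(ch)
    te <- ch$truth
    cbind(s$gx_beta - te$gx_effects, s$gy_beta - 0 * te$gx_effects)
  }, simplify = FALSE)
  e <- do.call(rbind, pairs)
  oracle_corr <- cor(e[, 1], e[, 2])
  set.seed(38)
  ch <- simulate_cohort(sc, draw_true_effects(sc))
  plug_in <- residual_correlation(ch, beta_hat = 0)$residual
  # oracle MC error: ~1500 error pairs, se(cor) ~ 0.026
  expect_lt(abs(plug_in - oracle_corr), 0.08)
})

test_that("mr_diagnostics assembles a consistent one-row report", {
  sc <- tiny_scenario(n_individuals = 3000L, n_snps = 20L,
                      causal_effect = 1, error_correlation = 0.2)
  set.seed(39)
  d <- simulate_design(sc)
  rep_full <- mr_diagnostics(d, full = TRUE)
  expect_equal(nrow(rep_full), 1L)
  expect_true(rep_full$frac_weak >= 0 && rep_full$frac_weak <= 1)
  expect_true(rep_full$igx2 >= 0 && rep_full$igx2 <= 1)
  expect_gte(rep_full$q_stat, 0)
  expect_equal(rep_full$r2_exposure,
               variance_explained(d$cohort_x, "exposure"), tolerance = 1e-10)
  rep_cheap <- mr_diagnostics(d, full = FALSE)
  expect_true(is.na(rep_cheap$r2_exposure))
  expect_equal(rep_cheap$mean_f, rep_full$mean_f, tolerance = 1e-12)
})
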