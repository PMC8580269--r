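test_that("Wald ratios follow the delta-method arithmetic", {
  r <- wald_ratios(ss(1, 0.1, 2, 0.5))
  expect_equal(r$ratios, 2, tolerance = 1e-12)
  expect_equal(r$ratio_se, 0.5, tolerance = 1e-12)

  r2 <- wald_ratios(ss(-2, 0.1, 3, 1))
  expect_equal(r2$ratios, -1.5, tolerance = 1e-12)
  expect_equal(r2$ratio_se, 0.5, tolerance = 1e-12)

  expect_warning(r3 <- wald_ratios(ss(c(0, 1), c(1, 1), c(1, 1), c(1, 1))),
                 "zero gene-exposure")
  expect_length(r3$ratios, 1L)

  # infinitely strong instrument: ratio and se collapse to zero
  r4 <- wald_ratios(ss(1e9, 1, 2, 1))
  expect_lt(abs(r4$ratios), 1e-8)
  expect_lt(r4$ratio_se, 1e-8)
})

test_that("IVW fixed-effect pools by inverse variance", {
  # single SNP: the meta-analysis is the ratio itself
  r1 <- rs(1.7, 0.3)
  e1 <- mr_ivw_fe(r1)
  expect_equal(e1$estimate, 1.7, tolerance = 1e-12)
  expect_equal(e1$se, 0.3, tolerance = 1e-12)

  # equal weights reduce to the plain mean
  e3 <- mr_ivw_fe(rs(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(e3$estimate, 2, tolerance = 1e-12)
  expect_equal(e3$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(e3$p_value, 2 * pnorm(-2 * sqrt(3)), tolerance = 1e-12)
})

test_that("multiplicative random effects inflate but never deflate the SE", {
  # no heterogeneity: phi floored at 1, SE equals fixed effect
  same <- rs(c(2, 2, 2), c(1, 2, 3))
  expect_equal(mr_ivw_mre(same)$se, mr_ivw_fe(same)$se, tolerance = 1e-12)

  # hand-computed overdispersion: Q = 8, phi = 4, SE doubled
  r <- rs(c(0, 2, 4), c(1, 1, 1))
  fe <- mr_ivw_fe(r)
  re <- mr_ivw_mre(r)
  expect_equal(cochran_q(r, fe$estimate), 8, tolerance = 1e-12)
  expect_equal(re$estimate, fe$estimate, tolerance = 1e-12)
  expect_equal(re$se, 2 * fe$se, tolerance = 1e-12)
  expect_error(mr_ivw_mre(rs(1, 1)), "at least 2")
})

test_that("FE and MRE point estimates are identical on random inputs", {
  set.seed(20)
  for (i in 1:25) {
    j <- sample(2:30, 1)
    r <- rs(rnorm(j), runif(j, 0.05, 2))
    expect_identical(mr_ivw_fe(r)$estimate, mr_ivw_mre(r)$estimate)
  }
})

test_that("weighted median matches its brute-force oracle", {
  # odd J, equal weights: the middle sorted ratio
  e <- mr_weighted_median(rs(c(5, 1, 3), c(1, 1, 1)), n_boot = 0)
  expect_equal(e$estimate, 3, tolerance = 1e-12)
  # outlier-robust
  e2 <- mr_weighted_median(rs(c(1, 2, 10), c(1, 1, 1)), n_boot = 0)
  expect_equal(e2$estimate, 2, tolerance = 1e-12)

  # unequal weights against the independent interpolation oracle
  b <- c(0.8, 1.1, 1.4, 3.0)
  se <- c(0.2, 0.1, 0.4, 0.15)
  e4 <- mr_weighted_median(rs(b, se), n_boot = 0)
  expect_equal(e4$estimate, oracle_weighted_median(b, 1 / se^2),
               tolerance = 1e-10)

  set.seed(21)
  for (i in 1:20) {
    j <- sample(3:12, 1)
    b <- rnorm(j); se <- runif(j, 0.05, 1)
    expect_equal(mr_weighted_median(rs(b, se), n_boot = 0)$estimate,
                 oracle_weighted_median(b, 1 / se^2), tolerance = 1e-10)
  }

  # permutation invariance
  b <- c(0.8, 1.1, 1.4, 3.0)
  se <- c(0.2, 0.1, 0.4, 0.15)
  o <- sample(4)
  expect_equal(mr_weighted_median(rs(b[o], se[o]), n_boot = 0)$estimate,
               mr_weighted_median(rs(b, se), n_boot = 0)$estimate,
               tolerance = 1e-12)
  expect_error(mr_weighted_median(rs(c(1, 2), c(1, 1))), "at least 3")
})

test_that("weighted median bootstrap SE is reproducible and sane", {
  r <- rs(c(0.9, 1.0, 1.2, 1.4, 0.7), c(0.1, 0.12, 0.2, 0.3, 0.15))
  set.seed(22)
  e1 <- mr_weighted_median(r, n_boot = 500)
  set.seed(22)
  e2 <- mr_weighted_median(r, n_boot = 500)
  expect_identical(e1$se, e2$se)
  expect_gt(e1$se, 0)
  expect_warning(mr_weighted_median(r, n_boot = 50), "unstable")
})

test_that("weighted mode matches a dense-grid kernel oracle", {
  # degenerate density: all ratios equal
  e0 <- mr_weighted_mode(rs(rep(1.3, 4), c(1, 2, 1, 2)), n_boot = 0)
  expect_equal(e0$estimate, 1.3, tolerance = 1e-12)

  # cluster of 8 near 1 plus 2 outliers at 3: mode stays in the cluster
  b <- c(0.9, 0.95, 1.0, 1.02, 1.05, 1.1, 0.98, 1.01, 3.0, 3.1)
  se <- rep(0.1, 10)
  e <- mr_weighted_mode(rs(b, se), n_boot = 0)
  expect_gt(e$estimate, 0.9)
  expect_lt(e$estimate, 1.1)
  expect_equal(e$estimate, oracle_weighted_mode(b, 1 / se^2),
               tolerance = 1e-8)

  set.seed(23)
  for (i in 1:10) {
    j <- sample(4:10, 1)
    b <- rnorm(j); se <- runif(j, 0.1, 0.5)
    expect_equal(mr_weighted_mode(rs(b, se), n_boot = 0)$estimate,
                 oracle_weighted_mode(b, 1 / se^2), tolerance = 1e-8)
  }
})

test_that("MR-Egger matches the weighted normal-equations oracle", {
  # exactly collinear points: intercept a, slope b, zero residual
  gx <- c(0.1, 0.2, 0.4)
  gy <- 0.05 + 2 * gx
  e <- mr_egger(ss(gx, rep(0.02, 3), gy, c(0.01, 0.02, 0.015)))
  expect_equal(e$estimate, 2, tolerance = 1e-10)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)

  # 5-SNP weighted fixture vs the closed-form WLS oracle
  gx <- c(0.12, 0.05, 0.3, 0.22, 0.08)
  gy <- c(0.3, 0.01, 0.5, 0.6, 0.1)
  gyse <- c(0.1, 0.05, 0.2, 0.12, 0.07)
  e5 <- mr_egger(ss(gx, rep(0.01, 5), gy, gyse))
  o <- oracle_egger(gx, gy, gyse)
  expect_equal(e5$estimate, o$slope, tolerance = 1e-10)
  expect_equal(e5$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(e5$se, o$se_slope, tolerance = 1e-10)
  expect_equal(e5$intercept_se, o$se_intercept, tolerance = 1e-10)
  # t(J-2) inference
  expect_equal(e5$p_value, 2 * pt(-abs(e5$estimate / e5$se), 3),
               tolerance = 1e-12)

  # orientation invariance: flipping the sign of both coordinates of a SNP
  flip <- c(1, -1, 1, -1, 1)
  ef <- mr_egger(ss(gx * flip, rep(0.01, 5), gy * flip, gyse))
  expect_equal(ef$estimate, e5$estimate, tolerance = 1e-12)
  expect_equal(ef$intercept, e5$intercept, tolerance = 1e-12)
  expect_error(mr_egger(ss(c(1, 2), c(1, 1), c(1, 1), c(1, 1))),
               "at least 3")
})

test_that("2SLS matches the projection-matrix oracle", {
  set.seed(24)
  g <- cbind(rbinom(10, 2, 0.4), rbinom(10, 2, 0.5))
  x <- 0.5 * g[, 1] + 0.2 * g[, 2] + rnorm(10)
  y <- 1.2 * x + rnorm(10)
  ch <- manual_cohort(g, x, y)
  e <- mr_tsls(ch)
  o <- oracle_tsls(g, x, y)
  expect_equal(e$estimate, o$slope, tolerance = 1e-10)
  expect_equal(e$se, o$se, tolerance = 1e-10)

  # just-identified case: 2SLS equals the cohort-level Wald ratio
  ch1 <- manual_cohort(g[, 1, drop = FALSE], x, y)
  wald <- cov(g[, 1], y) / cov(g[, 1], x)
  expect_equal(mr_tsls(ch1)$estimate, wald, tolerance = 1e-10)

  # rank-deficient first stage names the collinear column
  gdup <- cbind(g, g[, 1])
  expect_error(mr_tsls(manual_cohort(gdup, x, y)), "snp3")
})
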