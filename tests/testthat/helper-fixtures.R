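# Shared fixtures, all built in code.

# small, fast scenario for unit tests (not calibrated to the headline study)
tiny_scenario <- function(...) {
  args <- list(...)
  defaults <- list(n_individuals = 2000L, n_snps = 12L, seed = 42L)
  do.call(mr_scenario, utils::modifyList(defaults, args))
}

# wrap hand-written matrices/vectors as an mr_cohort
manual_cohort <- function(g, x, y, design = "one_sample") {
  g <- as.matrix(g)
  storage.mode(g) <- "double"
  sc <- mr_scenario(n_individuals = nrow(g), n_snps = ncol(g),
                    design = design)
  structure(list(genotypes = g, exposure = as.numeric(x),
                 outcome = as.numeric(y),
                 eps_x = NULL, eps_y = NULL, truth = NULL, scenario = sc),
            class = "mr_cohort")
}

# deterministic 6-individual toy cohort used by the regression oracles
toy6 <- function() {
  g <- c(0, 1, 2, 0, 1, 2)
  x <- c(0.3, 1.1, 2.2, -0.2, 1.4, 1.9)
  y <- c(0.5, 0.9, 2.5, 0.1, 1.2, 2.1)
  manual_cohort(cbind(g), x, y)
}

# build a summary set quickly from vectors
ss <- function(gx, gxse, gy, gyse) summary_set(gx, gxse, gy, gyse)

# ratio set from plain ratios/SEs (unit gene-exposure estimates so the
# Wald ratios equal the gene-outcome estimates)
rs <- function(ratios, se) wald_ratios(ss(rep(1, length(ratios)),
                                          rep(1e-6, length(ratios)),
                                          ratios, se))

# --- independent oracles (coded separately from the implementations) ---

# weighted median: explicit bracket-and-interpolate on cumulative weights
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(b[1])
  if (0.5 >= cw[length(cw)]) return(b[length(b)])
  i <- max(which(cw < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
}

# weighted mode: dense-grid argmax of the weighted gaussian kernel sum,
# refined by a root of the hand-derived density derivative
oracle_weighted_mode <- function(b, w, bandwidth_factor = 1) {
  h <- bandwidth_factor * 0.9 * min(sd(b), mad(b)) * length(b)^(-1 / 5)
  dens <- function(x)
    vapply(x, function(xx) sum(w * exp(-0.5 * ((xx - b) / h)^2)), 0)
  ddens <- function(x)
    sum(w * ((b - x) / h^2) * exp(-0.5 * ((x - b) / h)^2))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 20001L)
  i <- which.max(dens(grid))
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  uniroot(ddens, c(lo, hi), tol = 1e-14)$root
}

# Egger WLS: explicit normal equations (X'WX)^{-1} X'Wy after orientation
oracle_egger <- function(gx, gy, gyse) {
  flip <- ifelse(gx < 0, -1, 1)
  x <- gx * flip; y <- gy * flip
  X <- cbind(1, x)
  W <- diag(1 / gyse^2)
  coef <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  rss <- t(y - X %*% coef) %*% W %*% (y - X %*% coef)
  phi <- max(1, as.numeric(rss) / (length(x) - 2))
  vcv <- phi * solve(t(X) %*% W %*% X)
  list(intercept = coef[1], slope = coef[2],
       se_slope = sqrt(vcv[2, 2]), se_intercept = sqrt(vcv[1, 1]))
}

# 2SLS: explicit projection-matrix algebra on small fixtures
oracle_tsls <- function(g, x, y) {
  z <- cbind(1, as.matrix(g))
  pz <- z %*% solve(t(z) %*% z) %*% t(z)
  xhat <- as.vector(pz %*% x)
  X <- cbind(1, xhat)
  coef <- solve(t(X) %*% X, t(X) %*% y)
  u <- y - cbind(1, x) %*% coef       # residuals at observed exposure
  se <- sqrt(sum(u^2) / (length(y) - 2) /
               sum((xhat - mean(xhat))^2))
  list(slope = coef[2], se = se)
}
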