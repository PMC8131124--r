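# Gibbs animal model: conjugate degenerations, cross-sampler agreement,
# reproducibility, ratio arithmetic, diagnostics, and interval calibration.

test_that("priors equally partition the phenotypic variance", {
  y <- rnorm(200, sd = sqrt(207))
  pr <- default_priors(y, k_random = 2, nu = 1)
  expect_equal(pr$animal$V, var(y) / 3)
  expect_equal(pr$dam$V, var(y) / 3)
  expect_equal(pr$residual$V, var(y) / 3)
  pr0 <- default_priors(y, k_random = 0)
  expect_equal(pr0$residual$V, var(y))
  expect_null(pr0$animal)
  expect_error(default_priors(rep(1, 50)), "zero sample")
  expect_error(default_priors(c(1)), "at least two")
})

test_that("with no random effects the posterior mean equals the OLS solution", {
  set.seed(1)
  n <- 120
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta) + rnorm(n, sd = 2)
  res <- gibbs_mixed_reference(y, X, random = list(),
                               resid_prior = list(V = var(y), nu = 0.01),
                               n_iter = 8000, burn_in = 2000, seed = 3)
  bhat <- qr.solve(X, y)
  post <- colMeans(res$draws[, 1:3])
  # flat-prior Bayesian regression: posterior mean of beta is OLS
  se <- sqrt(diag(solve(crossprod(X))) * var(y))
  expect_true(all(abs(post - bhat) < 0.15 * se + 1e-3))
})

test_that("with known variances the posterior mean equals the GLS/BLUP solve", {
  set.seed(2)
  n_g <- 8; n_per <- 12
  g <- factor(rep(seq_len(n_g), each = n_per))
  u <- rnorm(n_g, sd = 2)
  y <- 5 + u[g] + rnorm(n_g * n_per, sd = 1.5)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "mu"))
  Z <- model.matrix(~ g - 1)
  s2u <- 4; s2e <- 2.25
  res <- gibbs_mixed_reference(
    y, X, random = list(grp = list(Z = Z, Ginv = diag(n_g), V = s2u, nu = 1)),
    resid_prior = list(V = s2e, nu = 1),
    n_iter = 12000, burn_in = 2000, seed = 4,
    fix_variances = c(grp = s2u, residual = s2e))
  # direct mixed-model-equations solution at the fixed variances
  W <- cbind(X, Z)
  C <- crossprod(W) / s2e + diag(c(1e-8, rep(1 / s2u, n_g)))
  sol <- solve(C, crossprod(W, y) / s2e)
  expect_equal(unname(colMeans(res$draws[, "mu", drop = FALSE])), sol[1],
               tolerance = 0.01)
  expect_equal(unname(res$effect_means$grp), unname(sol[-1]), tolerance = 0.05)
  # shrinkage identity of the balanced one-way BLUP
  lam <- n_per * s2u / (n_per * s2u + s2e)
  mu_hat <- sol[1]
  expect_equal(as.numeric(sol[-1]),
               as.numeric(lam * (tapply(y, g, mean) - mu_hat)), tolerance = 1e-8)
})

test_that("reduced and mixed-model-equation samplers target the same posterior", {
  sim <- small_recovery(seed = 4)
  mc <- function(seed) mcmc_settings_scaled(30000, 6000, 20, seed = seed)
  f1 <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes,
                     mcmc = mc(5), method = "reduced")
  f2 <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes,
                     mcmc = mc(9), method = "mme")
  for (p in c("sigma2_a", "sigma2_m", "sigma2_e")) {
    m1 <- mean(f1$draws[, p]); m2 <- mean(f2$draws[, p])
    s <- sd(f1$draws[, p])
    expect_lt(abs(m1 - m2), 0.35 * s)  # agreement within Monte Carlo error
  }
  expect_lt(abs(mean(f1$h2) - mean(f2$h2)), 0.06)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1.5)
})

test_that("null genetic and maternal variance concentrates h2 near zero", {
  p <- null_variance_params(25)
  sim <- simulate_recovery_dataset("LOW", 8, 14, 16, 15, params = p, seed = 6)
  fit <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes,
                      mcmc = mcmc_settings_scaled(20000, 4000, 16, seed = 6))
  expect_lt(mean(fit$h2), 0.2)
  expect_lt(variance_ratios(fit)["h2", "hpd_low"], 0.05)
  expect_lt(mean(fit$m2), 0.2)
})

test_that("chains are reproducible and invariant to phenotype row order", {
  sim <- small_recovery(seed = 7)
  mc <- mcmc_settings_scaled(4000, 1000, 3, seed = 11)
  f1 <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes, mcmc = mc)
  f2 <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes, mcmc = mc)
  expect_identical(f1$draws, f2$draws)
  perm <- sim$phenotypes[sample(nrow(sim$phenotypes)), ]
  f3 <- animal_model(length_um ~ dam_site + sire_site, perm, mcmc = mc)
  expect_identical(f1$draws, f3$draws)
})

test_that("variance ratios are exact arithmetic on the draws", {
  fake <- list(draws = cbind(sigma2_a = rep(140.7, 200),
                             sigma2_m = rep(22.76029, 200),
                             sigma2_e = rep(43.45147, 200)),
               h2 = rep(140.7 / 206.9118, 200),
               m2 = rep(22.76029 / 206.9118, 200))
  class(fake) <- "animal_model"
  vr <- variance_ratios(fake)
  expect_equal(vr["h2", "mean"], 0.68, tolerance = 1e-6)
  expect_equal(vr["m2", "mean"], 0.11, tolerance = 1e-6)
  # per-draw ratios sum to one
  sim <- small_recovery(seed = 8)
  fit <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes,
                      mcmc = mcmc_settings_scaled(3000, 500, 2, seed = 1))
  expect_true(all(abs(fit$h2 + fit$m2 +
                      fit$draws[, "sigma2_e"] /
                        rowSums(fit$draws[, c("sigma2_a", "sigma2_m", "sigma2_e")]) - 1)
                  < 1e-12))
  fake0 <- fake
  fake0$draws[, "sigma2_a"] <- 0
  fake0$h2 <- rep(0, 200)
  expect_equal(variance_ratios(fake0)["h2", "mean"], 0)
})

test_that("diagnostics flag autocorrelated chains and reward thinning", {
  set.seed(9)
  iid <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  d1 <- mcmc_diagnostics(iid)
  expect_true(attr(d1, "pass"))
  expect_true(all(abs(d1$lag1_autocorr) < 0.1))
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1000))
  d2 <- mcmc_diagnostics(cbind(ar = ar))
  expect_false(attr(d2, "pass"))
  expect_gt(d2$lag1_autocorr[1], 0.5)
  thinned <- ar[seq(1, length(ar), by = 10)]
  expect_lt(abs(acf(thinned, lag.max = 1, plot = FALSE)$acf[2]),
            abs(acf(ar, lag.max = 1, plot = FALSE)$acf[2]))
  expect_error(mcmc_diagnostics(iid[1:50, ]), "100")
})

test_that("prior-sensitivity runner sweeps the degrees of belief", {
  sim <- small_recovery(seed = 10)
  out <- prior_sensitivity(length_um ~ dam_site + sire_site, sim$phenotypes,
                           nu_values = c(0.002, 1),
                           mcmc = mcmc_settings_scaled(6000, 1500, 5, seed = 2))
  expect_equal(nrow(out), 2)
  expect_true(all(is.finite(out$h2_mode)))
  expect_true(all(out$h2_mode >= 0 & out$h2_mode <= 1))
})

test_that("degenerate model inputs raise errors", {
  sim <- small_recovery(seed = 12)
  expect_error(animal_model(length_um ~ dam_site, sim$phenotypes,
                            salinity = "BRACKISH"), "no phenotype")
})
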