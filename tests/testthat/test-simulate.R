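# Synthetic-data generator: determinism, degenerate cases, and agreement of
# the simulated variance structure with its closed forms.

test_that("the generator is a pure function of parameters and seed", {
  p <- default_params()
  a <- simulate_experiment(p, seed = 9, n_blocks = 3)
  b <- simulate_experiment(p, seed = 9, n_blocks = 3)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$founders, b$founders)
  expect_identical(a$survival, b$survival)
  expect_identical(a$eggs, b$eggs)
  d <- simulate_experiment(p, seed = 10, n_blocks = 3)
  expect_false(identical(a$phenotypes$length_um, d$phenotypes$length_um))
})

test_that("zero additive variance gives exactly zero breeding values", {
  cr <- ncii_cross_table(2, seed = 1)
  f <- simulate_founders(cr, null_variance_params(), seed = 1)
  expect_true(all(f$bv_low == 0) && all(f$bv_ambient == 0))
})

test_that("founder breeding-value variance obeys the law of large numbers", {
  # 5000 independent dams and sires drawn at sigma2_a = 140.7
  cr <- data.frame(block = 1, dam = sprintf("D%04d", 1:5000),
                   sire = sprintf("S%04d", 1:5000),
                   dam_site = "LOW", sire_site = "MEDIUM",
                   fertilized = NA, family = NA_character_,
                   stringsAsFactors = FALSE)
  f <- simulate_founders(cr, default_params(), seed = 2)
  expect_equal(var(f$bv_low), 140.7, tolerance = 0.05)
  expect_equal(var(f$bv_ambient), 122.3, tolerance = 0.05)
  expect_equal(cov(f$bv_low, f$bv_ambient), 55.18, tolerance = 0.10)
  dams <- f[f$sex == "dam", ]
  expect_equal(var(dams$mat_low), 140.7 / 0.68 * 0.11, tolerance = 0.10)
})

test_that("fertilization failure is Bernoulli with the configured rate", {
  p <- default_params()
  cr <- ncii_cross_table(16, seed = 1)
  n_surv <- vapply(1:20, function(s)
    sum(simulate_fertilization(cr, p, seed = s)$fertilized), 1L)
  expect_equal(mean(n_surv), 128 * 0.32, tolerance = 0.12)
  p$fertilization_failure_rate <- 0
  expect_true(all(simulate_fertilization(cr, p, 1)$fertilized))
  p$fertilization_failure_rate <- 1
  cr1 <- simulate_fertilization(cr, p, 1)
  expect_false(any(cr1$fertilized))
  expect_equal(nrow(simulate_larvae(cr1, simulate_founders(cr1, p, 1), p, 1)), 0)
})

test_that("all-zero variances and effects give every length equal to mu", {
  p <- null_variance_params(0)
  p$beta_salinity <- p$beta_dam_acclim <- p$beta_sire_acclim <- 0
  p$beta_dam_x_salinity <- p$beta_sire_x_salinity <- 0
  p$fertilization_failure_rate <- 0
  p$family_keep_prob <- 1; p$measure_rate <- list(low = 1, ambient = 1)
  cr <- simulate_fertilization(ncii_cross_table(1, seed = 1), p, 1)
  ph <- simulate_larvae(cr, simulate_founders(cr, p, 1), p, 1)
  expect_true(all(ph$length_um == p$mu))
})

test_that("full-sib intraclass correlation matches its closed form", {
  # ICC of full sibs = (sigma2_a/2 + sigma2_m) / Vp, single environment
  p <- default_params()
  icc_theory <- (140.7 / 2 + p$sigma2_m$low) /
    (140.7 + p$sigma2_m$low + p$sigma2_e$low)
  iccs <- vapply(1:40, function(r) {
    sim <- simulate_recovery_dataset("LOW", 12, 21, 27, 12, seed = 50 + r)
    ph <- sim$phenotypes
    a <- stats::aov(length_um ~ family_id, data = ph)
    ms <- summary(a)[[1]]$`Mean Sq`
    k <- 12
    (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  }, 1)
  expect_equal(mean(iccs), icc_theory, tolerance = 0.12)
})

test_that("grand ambient-vs-low size difference averages 3.4 um", {
  diffs <- vapply(1:8, function(s) {
    sim <- simulate_experiment(seed = 20 + s, n_blocks = 16)
    ph <- sim$phenotypes
    mean(ph$length_um[ph$salinity == "AMBIENT"]) -
      mean(ph$length_um[ph$salinity == "LOW"])
  }, 1)
  expect_equal(mean(diffs), 3.4, tolerance = 0.2)
})

test_that("survival simulation honours mean, dispersion and edge cases", {
  p <- default_params()
  cr <- simulate_fertilization(ncii_cross_table(8, seed = 1), p, 1)
  p$mortality_dispersion <- 0
  p$survival_n <- 5000
  sv <- simulate_survival(cr, p, seed = 3)
  expect_equal(mean(sv$mortality), 0.27, tolerance = 0.02)
  p$mortality_mean <- 0
  expect_true(all(simulate_survival(cr, p, 3)$n_dead == 0))
  p$mortality_mean <- 0.27
  expect_identical(simulate_survival(cr, p, 7), simulate_survival(cr, p, 7))
})

test_that("egg-quality generator covers degenerate and default structure", {
  dams <- data.frame(dam = sprintf("D%02d", 1:30),
                     dam_site = rep(c("LOW", "MEDIUM"), each = 15))
  p <- default_params()
  eggs <- simulate_egg_quality(dams, p, seed = 1)
  expect_equal(nrow(eggs), 30 * 6)
  expect_true(all(eggs$value > 0))
  p$egg_quality_sds <- lapply(p$egg_quality_sds, function(x) 0)
  e0 <- simulate_egg_quality(dams, p, seed = 1)
  spread <- tapply(e0$value, e0$assay, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("experiment-level egg assays use 15 dams per site", {
  sim <- simulate_experiment(seed = 4)
  dams <- unique(sim$eggs[, c("dam_id", "dam_site")])
  expect_equal(unname(table(dams$dam_site)["LOW"]), 15)
  expect_equal(unname(table(dams$dam_site)["MEDIUM"]), 15)
})

test_that("simulating larvae with unknown parents is an error", {
  p <- default_params()
  cr <- simulate_fertilization(ncii_cross_table(1, seed = 1), p, 1)
  f <- simulate_founders(cr, p, 1)
  f2 <- f[-1, ]
  if (any(cr$fertilized & (cr$sire == f$id[1] | cr$dam == f$id[1]))) {
    expect_error(simulate_larvae(cr, f2, p, 1), "missing")
  } else succeed()
})

test_that("recovery designs hit the requested parental counts", {
  cr <- recovery_design(12, 21, 27, seed = 1)
  fams <- cr[which(cr$fertilized), ]
  expect_equal(nrow(fams), 27)
  expect_equal(length(unique(fams$sire)), 12)
  expect_equal(length(unique(fams$dam)), 21)
  sim <- simulate_recovery_dataset("AMBIENT", 13, 24, 29, 10, seed = 2)
  expect_equal(length(unique(sim$phenotypes$sire_id)), 13)
  expect_equal(length(unique(sim$phenotypes$dam_id)), 24)
  expect_equal(nrow(sim$phenotypes), 29 * 10)
  expect_true(all(sim$phenotypes$salinity == "AMBIENT"))
})
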