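# REML mixed-model ANOVAs, Tukey contrasts, and the egg-quality battery.

test_that("without random terms the F test equals the classical one-way ANOVA", {
  set.seed(1)
  d <- data.frame(y = rnorm(40), g = rep(c("a", "b"), each = 20))
  fit <- fit_lmm(y ~ g, d, random = NULL)
  at <- anova_table(fit)
  ref <- anova(lm(y ~ g, d))
  expect_equal(at$F[1], ref$`F value`[1], tolerance = 1e-10)
  expect_equal(at$p[1], ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("a zero-variance random intercept reduces to the OLS F", {
  set.seed(2)
  d <- data.frame(y = rnorm(120), g = rep(c("a", "b"), each = 60),
                  dam_id = rep(sprintf("D%d", 1:12), each = 10))
  fit <- fit_lmm(y ~ g, d, random = "dam_id")
  expect_lt(fit$varcomp[["dam_id"]], 0.15)
  at <- anova_table(fit)
  ols <- anova(lm(y ~ g, d))
  expect_equal(at$F[1], ols$`F value`[1], tolerance = 0.15)
})

test_that("orthogonal balanced designs give identical marginal and sequential tests", {
  set.seed(3)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:10)
  d$y <- rnorm(nrow(d)) + (d$a == "x") * 0.5
  fit <- fit_lmm(y ~ a + b, d, random = NULL)
  at <- anova_table(fit)
  seq_tab <- anova(lm(y ~ a + b, d,
                      contrasts = list(a = "contr.sum", b = "contr.sum")))
  expect_equal(at$F[at$term == "a"], seq_tab["a", "F value"], tolerance = 1e-10)
  expect_equal(at$F[at$term == "b"], seq_tab["b", "F value"], tolerance = 1e-10)
})

test_that("three-way mixed ANOVA on synthetic data has thousands of denominator df", {
  sim <- simulate_experiment(no_gxe_params(), seed = 31, n_blocks = 16)
  fit <- fit_lmm(length_um ~ salinity * dam_site + salinity * sire_site,
                 sim$phenotypes)
  at <- anova_table(fit)
  expect_gt(at$df_den[at$term == "salinity"], 1000)
  expect_gt(at$F[at$term == "salinity"], 10)
  expect_true(all(c("dam_id", "sire_id", "residual") %in% names(fit$varcomp)))
})

test_that("null-effect p-values are uniform (type-I calibration)", {
  set.seed(4)
  pvals <- replicate(200, {
    d <- data.frame(y = rnorm(60), g = sample(rep(c("a", "b"), 30)))
    anova_table(fit_lmm(y ~ g, d, random = NULL))$p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("the calibrated salinity effect is detected with near-certain power", {
  for (s in 1:2) {
    sim <- simulate_experiment(no_gxe_params(), seed = 40 + s)
    at <- anova_table(fit_lmm(length_um ~ salinity + dam_site + sire_site,
                              sim$phenotypes))
    expect_lt(at$p[at$term == "salinity"], 0.001)
  }
})

test_that("Tukey with two cells equals the unadjusted comparison", {
  set.seed(5)
  d <- data.frame(y = rnorm(50) + rep(c(0, 1), 25), g = rep(c("a", "b"), 25))
  fit <- fit_lmm(y ~ g, d, random = NULL)
  tk <- tukey_contrasts(fit, "g")
  tt <- summary(lm(y ~ g, d, contrasts = list(g = "contr.sum")))
  expect_equal(nrow(tk), 1)
  expect_equal(tk$p_tukey, 2 * pt(-abs(tk$t), tk$df), tolerance = 1e-8)
})

test_that("Tukey adjustment is monotone and percent differences use the smaller cell", {
  set.seed(6)
  d <- expand.grid(g = c("a", "b", "c"), rep = 1:15)
  d$y <- 50 + (d$g == "b") * 3 + rnorm(nrow(d))
  fit <- fit_lmm(y ~ g, d, random = NULL)
  tk <- tukey_contrasts(fit, "g")
  em <- emmeans::emmeans(fit$fit, "g", data = fit$data)
  unadj <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))$p.value
  expect_true(all(tk$p_tukey >= unadj - 1e-12))
  expect_true(all(tk$pct_diff >= 0))  # "X% larger" convention
  cells <- summary(em)
  i <- which(tk$contrast == "a - b")
  expect_equal(tk$pct_diff[i],
               100 * abs(tk$estimate[i]) / min(cells$emmean[cells$g %in% c("a", "b")]),
               tolerance = 1e-8)
})

test_that("empty interaction cells are reported by name", {
  d <- data.frame(y = rnorm(30), g = rep(c("a", "b"), 15),
                  h = c(rep("u", 15), rep("v", 15)))
  d <- d[!(d$g == "a" & d$h == "v"), ]
  fit <- fit_lmm(y ~ g + h, d, random = NULL)
  expect_error(tukey_contrasts(fit, c("g", "h")), "empty")
})

test_that("Satterthwaite helper reproduces the Welch two-sample df exactly", {
  s1 <- 2.3; s2 <- 0.9; n1 <- 11; n2 <- 23
  v <- c(s1^2 / n1, s2^2 / n2)
  welch <- (s1^2 / n1 + s2^2 / n2)^2 /
    ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  expect_equal(satterthwaite_df(v, c(n1 - 1, n2 - 1)), welch, tolerance = 1e-12)
})

test_that("REML matches the closed-form ANOVA estimator on a balanced one-way design", {
  set.seed(7)
  n_g <- 12; k <- 8
  g <- rep(sprintf("D%02d", 1:n_g), each = k)
  y <- 10 + rnorm(n_g, sd = 2)[as.integer(factor(g))] + rnorm(n_g * k)
  d <- data.frame(y = y, dam_id = g)
  fit <- fit_lmm(y ~ 1, d, random = "dam_id")
  a <- anova(lm(y ~ g))
  msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
  expect_equal(fit$varcomp[["dam_id"]], max((msb - msw) / k, 0), tolerance = 1e-6)
  expect_equal(fit$varcomp[["residual"]], msw, tolerance = 1e-6)
})

test_that("factors with a single level are rejected", {
  d <- data.frame(y = rnorm(10), g = "a")
  expect_error(fit_lmm(y ~ g, d, random = NULL), "fewer than 2")
})

test_that("egg-quality battery is calibrated under the null and powered under a site shift", {
  p <- default_params()
  dams <- data.frame(dam = sprintf("D%02d", 1:30),
                     dam_site = rep(c("LOW", "MEDIUM"), each = 15))
  reject <- vapply(1:120, function(r) {
    eggs <- simulate_egg_quality(dams, p, seed = 7000 + r)
    mean(egg_quality_tests(eggs)$site_p < 0.05)
  }, 1)
  expect_lt(abs(mean(reject) - 0.05), 0.05)
  # injected 2-fold site effect on the natural scale
  p2 <- p; p2$egg_site_effect <- log(2)
  eggs2 <- simulate_egg_quality(dams, p2, seed = 99)
  expect_true(all(egg_quality_tests(eggs2)$site_p < 0.01))
})

test_that("egg-quality battery rejects degenerate inputs", {
  dams <- data.frame(dam = sprintf("D%02d", 1:30),
                     dam_site = rep(c("LOW", "MEDIUM"), each = 15))
  p <- default_params()
  eggs <- simulate_egg_quality(dams, p, seed = 1)
  eggs$value[1] <- -1
  expect_error(egg_quality_tests(eggs), "positive")
  p$egg_quality_sds <- lapply(p$egg_quality_sds, function(x) 0)
  e0 <- simulate_egg_quality(dams, p, seed = 1)
  expect_error(egg_quality_tests(e0), "zero variance")
  e1 <- simulate_egg_quality(dams[c(1, 16), ], default_params(), seed = 1)
  expect_error(egg_quality_tests(e1), "2 dams")
})

test_that("egg quality shows no link to larval size under the default generator", {
  sim <- simulate_experiment(seed = 51, n_blocks = 8)
  out <- egg_quality_tests(sim$eggs, sim$phenotypes)
  expect_true(all(c("slope", "slope_p") %in% names(out)))
  expect_gt(mean(out$slope_p > 0.05, na.rm = TRUE), 0.5)
})
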