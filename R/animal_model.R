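# Bayesian animal model: Gibbs-sampled variance components (additive
# genetic, maternal, residual), narrow-sense heritability and maternal
# ratio, fitted separately per rearing salinity.

#' MCMC settings for the Gibbs samplers
#'
#' `mcmc_settings()` defaults mirror the production run lengths (1.3M
#' iterations, 300k burn-in, thinned to ~1000 retained draws);
#' `mcmc_settings_scaled()` is the scaled-down configuration (50k/10k,
#' ~1000 retained) used for simulation studies and tests.
#'
#' @param n_iter Total iterations.
#' @param burn_in Discarded initial iterations (`< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw (`>= 1`).
#' @param seed Integer seed for the sampler stream.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 1300000, burn_in = 300000, thin = 1000,
                          seed = 1) {
  stopifnot(burn_in < n_iter, thin >= 1, n_iter > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
mcmc_settings_scaled <- function(n_iter = 50000, burn_in = 10000, thin = 40,
                                 seed = 1) {
  mcmc_settings(n_iter, burn_in, thin, seed)
}

#' Equal-partition priors for the variance components
#'
#' Each of the `k_random + 1` variance terms (random effects plus residual)
#' receives a scaled inverse-chi-square prior with scale `V = ` sample
#' phenotypic variance `/ (k_random + 1)` and small degrees of belief `nu`
#' (the univariate form of the inverse-Wishart: `IW(nu, nu * V)`), i.e. the
#' prior partitions the observed variance equally among all random terms.
#' Fixed effects get flat `N(0, 1e8)` priors.
#'
#' @param phenotypes Phenotype table (uses `length_um`) or a numeric vector.
#' @param k_random Number of random-effect variance terms besides the
#'   residual (2 for the animal + maternal model).
#' @param nu Degrees of belief per component (default 1).
#' @return List of class `prior_spec` with elements `animal`, `dam`,
#'   `residual` (each `list(V, nu)`); `animal`/`dam` dropped as `k_random`
#'   shrinks.
#' @export
default_priors <- function(phenotypes, k_random = 2, nu = 1) {
  y <- if (is.numeric(phenotypes)) phenotypes else phenotypes$length_um
  if (length(y) < 2) stop("need at least two phenotype records")
  vp <- stats::var(y)
  if (vp <= 0) stop("zero sample phenotypic variance; priors undefined")
  V <- vp / (k_random + 1)
  comp <- list(residual = list(V = V, nu = nu))
  if (k_random >= 1) comp$dam <- list(V = V, nu = nu)
  if (k_random >= 2) comp$animal <- list(V = V, nu = nu)
  structure(rev(comp), class = "prior_spec")
}

#' Fit the univariate animal model by Gibbs sampling
#'
#' Estimates additive genetic, maternal (dam identity), and residual
#' variance for larval size in one rearing salinity, with parental
#' acclimation sites as fixed effects and the pedigree carrying the additive
#' covariance structure:
#' `length = mu + DamAcclim + SireAcclim + Animal + DamID + e`.
#'
#' Two exact samplers are available. `"reduced"` (the default for the
#' package's strictly two-generation pedigrees) decomposes each offspring
#' breeding value into midparent plus an independent Mendelian deviation, so
#' the joint Gaussian location block is small and mixing is fast; `"mme"`
#' runs the generic mixed-model-equations sampler over all pedigree
#' individuals with the sparse inverse relationship matrix. Both target the
#' same posterior.
#'
#' @param formula Fixed-effect formula, e.g. `length_um ~ dam_site +
#'   sire_site`. The response must name a column of `data`.
#' @param data Phenotype table with columns `larva_id, dam_id, sire_id` plus
#'   the formula variables.
#' @param salinity Optional value of `data$salinity` to subset to (the model
#'   is fitted per rearing environment).
#' @param priors `prior_spec` from [default_priors()] (computed from the
#'   data if `NULL`).
#' @param mcmc [mcmc_settings()]; defaults to the scaled configuration.
#' @param method `"auto"`, `"reduced"`, or `"mme"`.
#' @return An object of class `animal_model`: retained draws of fixed
#'   effects and variance components, per-draw `h2`/`m2`, posterior means of
#'   founder breeding values and maternal effects, and fitting metadata.
#'   Methods: `print`, `summary`, `coef`, `plot`, [variance_ratios()],
#'   [mcmc_diagnostics()].
#' @examples
#' \donttest{
#' sim <- simulate_recovery_dataset("LOW", n_families = 8, n_per_family = 15,
#'                                  seed = 7)
#' fit <- animal_model(length_um ~ dam_site + sire_site, sim$phenotypes,
#'                     mcmc = mcmc_settings_scaled(6000, 1000, 5))
#' summary(fit)
#' }
#' @export
animal_model <- function(formula, data, salinity = NULL, priors = NULL,
                         mcmc = mcmc_settings_scaled(),
                         method = c("auto", "reduced", "mme")) {
  method <- match.arg(method)
  cl <- match.call()
  if (!is.null(salinity)) data <- data[data$salinity %in% salinity, , drop = FALSE]
  if (nrow(data) == 0) stop("no phenotype records to fit")
  stopifnot(all(c("larva_id", "dam_id", "sire_id") %in% names(data)))
  data <- data[order(data$larva_id), , drop = FALSE]  # label invariance

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  p <- ncol(X)
  sires <- sort(unique(data$sire_id))
  dams <- sort(unique(data$dam_id))
  n <- length(y)
  n_f <- length(sires) + length(dams)
  founder_ids <- c(sires, dams)

  if (is.null(priors)) priors <- default_priors(y, k_random = 2)
  if (method == "auto") method <- "reduced"

  if (method == "reduced") {
    W <- matrix(0, n, p + n_f + length(dams))
    W[, seq_len(p)] <- X
    fs <- p + match(data$sire_id, founder_ids)
    fd <- p + match(data$dam_id, founder_ids)
    md <- p + n_f + match(data$dam_id, dams)
    ij <- cbind(seq_len(n), fs); W[ij] <- W[ij] + 0.5
    ij <- cbind(seq_len(n), fd); W[ij] <- W[ij] + 0.5
    ij <- cbind(seq_len(n), md); W[ij] <- 1
    set.seed(substream_seed(mcmc$seed, "gibbs_animal"))
    res <- gibbs_reduced_cpp(
      y, W,
      founder_cols = as.integer(p + seq_len(n_f) - 1L),
      dam_cols = as.integer(p + n_f + seq_along(dams) - 1L),
      p_fixed = p,
      Va = priors$animal$V, nu_a = priors$animal$nu,
      Vm = priors$dam$V, nu_m = priors$dam$nu,
      Ve = priors$residual$V, nu_e = priors$residual$nu,
      n_iter = mcmc$n_iter, burn_in = mcmc$burn_in, thin = mcmc$thin)
    draws <- res$draws
    colnames(draws) <- c(colnames(X), "sigma2_a", "sigma2_m", "sigma2_e")
    eff <- res$effect_means
    breeding_values <- stats::setNames(eff[p + seq_len(n_f)], founder_ids)
    maternal_effects <- stats::setNames(eff[p + n_f + seq_along(dams)], dams)
  } else {
    ped <- pedigree_from_phenotypes(data)
    Ainv <- as.matrix(inverse_relationship_matrix(ped))
    Zan <- matrix(0, n, nrow(ped))
    Zan[cbind(seq_len(n), match(data$larva_id, ped$id))] <- 1
    Zdam <- matrix(0, n, length(dams))
    Zdam[cbind(seq_len(n), match(data$dam_id, dams))] <- 1
    res <- gibbs_mixed_reference(
      y, X,
      random = list(animal = list(Z = Zan, Ginv = Ainv,
                                  V = priors$animal$V, nu = priors$animal$nu),
                    dam = list(Z = Zdam, Ginv = diag(length(dams)),
                               V = priors$dam$V, nu = priors$dam$nu)),
      resid_prior = priors$residual,
      n_iter = mcmc$n_iter, burn_in = mcmc$burn_in, thin = mcmc$thin,
      seed = mcmc$seed)
    draws <- res$draws
    vc <- c("sigma2_animal", "sigma2_dam")
    colnames(draws)[match(vc, colnames(draws))] <- c("sigma2_a", "sigma2_m")
    breeding_values <- stats::setNames(
      res$effect_means$animal[match(founder_ids, ped$id)], founder_ids)
    maternal_effects <- stats::setNames(res$effect_means$dam, dams)
  }

  vtot <- draws[, "sigma2_a"] + draws[, "sigma2_m"] + draws[, "sigma2_e"]
  obj <- list(draws = draws,
              h2 = draws[, "sigma2_a"] / vtot,
              m2 = draws[, "sigma2_m"] / vtot,
              fixed_names = colnames(X),
              breeding_values = breeding_values,
              maternal_effects = maternal_effects,
              priors = priors, mcmc = mcmc, method = method,
              n = n, n_families = length(unique(data$family_id %||% data$dam_id)),
              n_sires = length(sires), n_dams = length(dams),
              salinity = salinity, call = cl)
  class(obj) <- "animal_model"
  obj
}

#' Posterior summaries of heritability and maternal ratio
#'
#' Per retained draw, `h2 = sigma2_a / (sigma2_a + sigma2_m + sigma2_e)` and
#' `m2 = sigma2_m / (same denominator)` (component-ratio convention: the
#' denominator excludes fixed-effect variance). The two ratios plus the
#' residual ratio sum to one in every draw.
#'
#' @param fit An `animal_model`.
#' @param prob Credible-interval mass.
#' @return `data.frame` (rows `h2`, `m2`, `e2`) with posterior mean, mode,
#'   SD, HPD and quantile intervals.
#' @export
variance_ratios <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "animal_model"))
  e2 <- 1 - fit$h2 - fit$m2
  comp <- list(h2 = fit$h2, m2 = fit$m2, e2 = e2)
  out <- do.call(rbind, lapply(names(comp), function(nm) {
    x <- comp[[nm]]
    h <- hpd_interval(x, prob)
    q <- stats::quantile(x, c((1 - prob) / 2, 1 - (1 - prob) / 2))
    data.frame(ratio = nm, mean = mean(x), mode = posterior_mode(x),
               sd = stats::sd(x), hpd_low = h[1], hpd_high = h[2],
               q_low = unname(q[1]), q_high = unname(q[2]))
  }))
  rownames(out) <- out$ratio
  out
}

#' MCMC convergence diagnostics
#'
#' Reports lag-1 autocorrelation, effective sample size, and summary
#' statistics per parameter, with a PASS flag when `|lag-1 autocorrelation|`
#' is below `lag1_threshold` and ESS above `ess_threshold` for every
#' parameter.
#'
#' @param x An `animal_model`, `family_covariance_model`, or a numeric
#'   matrix of draws (columns = parameters).
#' @param lag1_threshold,ess_threshold Convergence flags thresholds.
#' @return Object of class `mcmc_diagnostics` (a `data.frame` per parameter
#'   plus attribute `pass`).
#' @export
mcmc_diagnostics <- function(x, lag1_threshold = 0.1, ess_threshold = 200) {
  draws <- if (is.matrix(x)) x else x$draws
  if (is.null(dim(draws))) draws <- cbind(draws = draws)
  if (nrow(draws) < 100) stop("need at least 100 retained draws for diagnostics")
  out <- do.call(rbind, lapply(colnames(draws) %||% paste0("V", seq_len(ncol(draws))),
    function(nm) {
      v <- draws[, nm]
      lag1 <- if (stats::sd(v) == 0) 0 else
        stats::acf(v, lag.max = 1, plot = FALSE)$acf[2]
      data.frame(parameter = nm, mean = mean(v), sd = stats::sd(v),
                 lag1_autocorr = lag1, ess = effective_size(v),
                 pass = abs(lag1) < lag1_threshold & effective_size(v) > ess_threshold)
    }))
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("mcmc_diagnostics", "data.frame")
  out
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics:", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Prior-sensitivity sweep for the animal model
#'
#' Refits the model under alternative degrees-of-belief values of the
#' equal-partition prior and reports the posterior mean/mode of h2.
#'
#' @param formula,data,salinity,mcmc As in [animal_model()].
#' @param nu_values Degrees-of-belief values to sweep.
#' @return `data.frame` with one row per `nu`.
#' @export
prior_sensitivity <- function(formula, data, salinity = NULL,
                              nu_values = c(0.002, 1, 3),
                              mcmc = mcmc_settings_scaled()) {
  out <- lapply(nu_values, function(nu) {
    pr <- default_priors(if (is.null(salinity)) data$length_um else
      data$length_um[data$salinity %in% salinity], k_random = 2, nu = nu)
    fit <- animal_model(formula, data, salinity = salinity, priors = pr,
                        mcmc = mcmc)
    data.frame(nu = nu, h2_mean = mean(fit$h2), h2_mode = posterior_mode(fit$h2))
  })
  do.call(rbind, out)
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Bayesian animal model (Gibbs,", x$method, "sampler)\n")
  cat(sprintf("  %d larvae, %d sires, %d dams%s\n", x$n, x$n_sires, x$n_dams,
              if (!is.null(x$salinity)) paste0(", salinity = ", x$salinity) else ""))
  cat(sprintf("  %d retained draws (%d iterations, %d burn-in, thin %d)\n",
              nrow(x$draws), x$mcmc$n_iter, x$mcmc$burn_in, x$mcmc$thin))
  vr <- variance_ratios(x)
  cat(sprintf("  h2: mode %.2f (HPD95 %.2f-%.2f); m2: mode %.2f (HPD95 %.2f-%.2f)\n",
              vr["h2", "mode"], vr["h2", "hpd_low"], vr["h2", "hpd_high"],
              vr["m2", "mode"], vr["m2", "hpd_low"], vr["m2", "hpd_high"]))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, prob = 0.95, ...) {
  draws <- object$draws
  tab <- do.call(rbind, lapply(colnames(draws), function(nm) {
    v <- draws[, nm]
    h <- hpd_interval(v, prob)
    data.frame(parameter = nm, mean = mean(v), mode = posterior_mode(v),
               sd = stats::sd(v), hpd_low = h[1], hpd_high = h[2],
               ess = effective_size(v))
  }))
  rownames(tab) <- NULL
  out <- list(parameters = tab, ratios = variance_ratios(object, prob),
              n = object$n, mcmc = object$mcmc, method = object$method)
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  cat("Posterior summaries (", nrow(x$parameters), " parameters, ",
      x$n, " larvae)\n", sep = "")
  print.data.frame(x$parameters, digits = 4, row.names = FALSE)
  cat("\nVariance ratios:\n")
  print.data.frame(x$ratios, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) {
  colMeans(object$draws[, object$fixed_names, drop = FALSE])
}

#' @export
plot.animal_model <- function(x, pars = c("sigma2_a", "sigma2_m", "sigma2_e"), ...) {
  pars <- intersect(pars, colnames(x$draws))
  old <- graphics::par(mfrow = c(length(pars), 2), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in pars) {
    v <- x$draws[, nm]
    graphics::plot(v, type = "l", xlab = "", ylab = nm,
                   main = paste("trace:", nm), cex.main = 0.9)
    graphics::plot(stats::density(v), main = paste("density:", nm),
                   xlab = "", cex.main = 0.9)
  }
  invisible(x)
}
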