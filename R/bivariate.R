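# Bivariate family-mean model: additive genetic covariance of larval size
# between low- and ambient-salinity rearing, with family as the "animal".

#' Fit the bivariate family-mean covariance model
#'
#' Family-mean larval size in the two rearing environments is modelled as
#' `y[f, e] = mu_e + g[f, e] + eps[f, e]`, with family-level genetic effects
#' `vec(g) ~ N(0, G (x) A_fam)` where `G` is a 2x2 genetic covariance matrix
#' under an inverse-Wishart prior and `A_fam` the family relationship matrix
#' built from shared sires/dams (`linked = TRUE`) or the identity
#' (`linked = FALSE`). Residual covariance is forced diagonal (different
#' larvae are measured in each environment). Families observed in only one
#' environment contribute through their observed cell (missing at random).
#'
#' @param family_means Table from [family_mean_table()] or
#'   [simulate_family_means()] (columns `family, dam, sire, mean_low,
#'   mean_ambient`).
#' @param priors Optional list with `nu` (inverse-Wishart degrees of belief,
#'   default 2, the minimal proper value for a 2x2 covariance), `V` (2x2
#'   prior scale parameter; the scale matrix is `nu * V`; default
#'   equal-partition, `diag` of half the sample variances), and `resid`
#'   (`list(V, nu)` per-environment residual prior, default equal-partition
#'   with `nu = 1`).
#' @param mcmc [mcmc_settings()]; a scaled default is used if `NULL`.
#' @param linked Use pedigree links between families (default) or treat
#'   families as unrelated.
#' @return Object of class `family_covariance_model` with draws of
#'   `G11, G12, G22`, the genetic correlation `r_g`, environment means and
#'   residual variances. Methods: `print`, `summary`, [mcmc_diagnostics()].
#' @export
fit_bivariate_family_model <- function(family_means, priors = NULL,
                                       mcmc = NULL, linked = TRUE) {
  fm <- family_means
  stopifnot(all(c("family", "dam", "sire", "mean_low", "mean_ambient") %in% names(fm)))
  Y <- as.matrix(fm[, c("mean_low", "mean_ambient")])
  obs <- !is.na(Y)
  if (sum(rowSums(obs) > 0) < 3) stop("need at least 3 families with data")
  if (sum(obs[, 1] & obs[, 2]) == 0)
    stop("no family observed in both environments; covariance unidentifiable")
  if (is.null(mcmc)) mcmc <- mcmc_settings_scaled(12000, 2000, 10)

  Fn <- nrow(fm)
  A <- if (linked) family_relationship_matrix(fm) else diag(Fn)
  Ainv <- solve(A)

  vy <- apply(Y, 2, function(v) stats::var(v[!is.na(v)]))
  vy[is.na(vy) | vy <= 0] <- mean(vy, na.rm = TRUE)
  if (is.null(priors)) priors <- list()
  nu0 <- priors$nu %||% 2
  S0 <- nu0 * (priors$V %||% diag(vy / 2))
  resid_prior <- priors$resid %||% list(V = vy / 2, nu = 1)

  G <- diag(vy / 2)
  s2r <- resid_prior$V
  mu <- colMeans(Y, na.rm = TRUE)
  g <- matrix(0, Fn, 2)

  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  draws <- matrix(NA_real_, n_keep, 8,
                  dimnames = list(NULL, c("G11", "G12", "G22", "r_g",
                                          "mu_low", "mu_ambient",
                                          "sigma2_res_low", "sigma2_res_ambient")))
  kept <- 0L
  Dobs <- cbind(as.numeric(obs[, 1]), as.numeric(obs[, 2]))
  set.seed(substream_seed(mcmc$seed, "gibbs_bivariate"))

  for (it in seq_len(mcmc$n_iter)) {
    # means | g, residuals (flat prior)
    for (e in 1:2) {
      oe <- obs[, e]
      mu[e] <- mean(Y[oe, e] - g[oe, e]) +
        stats::rnorm(1, 0, sqrt(s2r[e] / sum(oe)))
    }
    # g | rest: joint 2F-dim Gaussian, precision Ginv (x) Ainv + obs/s2r
    Ginv <- solve(G)
    P <- kronecker(Ginv, Ainv)
    r <- numeric(2 * Fn)
    for (e in 1:2) {
      idx <- (e - 1) * Fn + seq_len(Fn)
      dg <- Dobs[, e] / s2r[e]
      P[cbind(idx, idx)] <- P[cbind(idx, idx)] + dg
      yc <- ifelse(obs[, e], Y[, e] - mu[e], 0)
      r[idx] <- yc / s2r[e] * Dobs[, e]
    }
    L <- chol(P)
    gv <- backsolve(L, forwardsolve(t(L), r)) + backsolve(L, stats::rnorm(2 * Fn))
    g <- matrix(gv, Fn, 2)
    # G | g: inverse-Wishart with scale S0 + g' Ainv g
    M <- crossprod(g, Ainv %*% g)
    G <- rinvwishart(nu0 + Fn, S0 + M)
    # residuals | rest
    for (e in 1:2) {
      oe <- obs[, e]
      ee <- Y[oe, e] - mu[e] - g[oe, e]
      s2r[e] <- (resid_prior$nu * resid_prior$V[e] + sum(ee^2)) /
        stats::rchisq(1, resid_prior$nu + sum(oe))
      s2r[e] <- max(s2r[e], 1e-10)
    }
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(G[1, 1], G[1, 2], G[2, 2],
                         G[1, 2] / sqrt(G[1, 1] * G[2, 2]),
                         mu[1], mu[2], s2r[1], s2r[2])
    }
  }
  obj <- list(draws = draws, n_families = Fn, linked = linked,
              priors = list(nu0 = nu0, S0 = S0, resid = resid_prior),
              mcmc = mcmc, call = match.call())
  class(obj) <- "family_covariance_model"
  obj
}

#' @export
print.family_covariance_model <- function(x, ...) {
  cat("Bivariate family-mean covariance model (", x$n_families, " families, ",
      if (x$linked) "pedigree-linked" else "unlinked", ")\n", sep = "")
  s <- summary(x)
  print.data.frame(s$parameters, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.family_covariance_model <- function(object, prob = 0.95, ...) {
  tab <- do.call(rbind, lapply(colnames(object$draws), function(nm) {
    v <- object$draws[, nm]
    h <- hpd_interval(v, prob)
    data.frame(parameter = nm, mean = mean(v), mode = posterior_mode(v),
               hpd_low = h[1], hpd_high = h[2], ess = effective_size(v))
  }))
  rownames(tab) <- NULL
  out <- list(parameters = tab, n_families = object$n_families)
  class(out) <- "summary.family_covariance_model"
  out
}

#' @export
print.summary.family_covariance_model <- function(x, ...) {
  print.data.frame(x$parameters, digits = 4, row.names = FALSE)
  invisible(x)
}
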