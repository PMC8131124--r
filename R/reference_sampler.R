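# Generic mixed-model-equations Gibbs sampler (reference implementation).
#
# Dense and deliberately simple: the joint location block (fixed effects and
# all random-effect levels) is drawn from its Gaussian full conditional via
# the mixed-model equations, then each variance component from its scaled
# inverse-chi-square full conditional. Used for arbitrary pedigrees (via the
# sparse inverse relationship matrix densified), for conjugate-case
# validation, and as the independent cross-check of the fast reduced
# sampler.

#' Reference Gibbs sampler for Gaussian mixed models
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (may have zero columns).
#' @param random Named list of random terms, each
#'   `list(Z = incidence matrix, Ginv = precision structure (identity or
#'   inverse relationship matrix), V = prior scale, nu = prior df)`.
#' @param resid_prior `list(V, nu)` for the residual variance.
#' @param n_iter,burn_in,thin Chain settings.
#' @param seed Integer seed.
#' @param fix_variances Optional named numeric vector holding selected
#'   variances fixed (names among the random-term names and `"residual"`);
#'   fixed components are never updated, giving the known-variance (GLS)
#'   degeneration.
#' @return List with `draws` (matrix: fixed effects, `sigma2_<term>` per
#'   random term, `sigma2_e`) and `effect_means` (posterior-mean random
#'   effects per term).
#' @export
gibbs_mixed_reference <- function(y, X, random = list(),
                                  resid_prior = list(V = stats::var(y), nu = 1),
                                  n_iter = 5000, burn_in = 1000, thin = 1,
                                  seed = 1, fix_variances = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (p > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("beta", seq_len(p))
  k <- length(random)
  if (k > 0 && is.null(names(random))) names(random) <- paste0("u", seq_len(k))
  qs <- vapply(random, function(r) ncol(r$Z), integer(1))
  W <- do.call(cbind, c(list(X), lapply(random, `[[`, "Z")))
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  qtot <- ncol(W)
  blocks <- if (k > 0) split(p + seq_len(sum(qs)), rep(seq_len(k), qs)) else list()

  s2 <- vapply(random, `[[`, numeric(1), "V")
  s2e <- resid_prior$V
  fixed_flag <- function(nm) !is.null(fix_variances) && nm %in% names(fix_variances)
  for (nm in names(random)) if (fixed_flag(nm)) s2[nm] <- fix_variances[[nm]]
  if (fixed_flag("residual")) s2e <- fix_variances[["residual"]]

  n_keep <- (n_iter - burn_in) %/% thin
  draws <- matrix(NA_real_, n_keep,
                  p + k + 1,
                  dimnames = list(NULL, c(colnames(X),
                                          if (k) paste0("sigma2_", names(random)),
                                          "sigma2_e")))
  eff_sum <- lapply(blocks, function(b) numeric(length(b)))
  kept <- 0L
  set.seed(substream_seed(seed, "gibbs_reference"))

  for (it in seq_len(n_iter)) {
    C <- WtW / s2e
    if (p > 0) for (j in seq_len(p)) C[j, j] <- C[j, j] + 1e-8
    for (ki in seq_len(k)) {
      b <- blocks[[ki]]
      C[b, b] <- C[b, b] + random[[ki]]$Ginv / s2[ki]
    }
    L <- chol(C)  # upper triangular
    mu_g <- backsolve(L, forwardsolve(t(L), Wty / s2e))
    g <- mu_g + backsolve(L, stats::rnorm(qtot))

    for (ki in seq_len(k)) {
      nm <- names(random)[ki]
      if (!fixed_flag(nm)) {
        u <- g[blocks[[ki]]]
        ss <- drop(crossprod(u, random[[ki]]$Ginv %*% u))
        s2[ki] <- (random[[ki]]$nu * random[[ki]]$V + ss) /
          stats::rchisq(1, random[[ki]]$nu + qs[ki])
        s2[ki] <- max(s2[ki], 1e-10)
      }
    }
    if (!fixed_flag("residual")) {
      e <- y - W %*% g
      s2e <- (resid_prior$nu * resid_prior$V + sum(e^2)) /
        stats::rchisq(1, resid_prior$nu + n)
      s2e <- max(s2e, 1e-10)
    }

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(if (p > 0) g[seq_len(p)], s2, s2e)
      for (ki in seq_len(k))
        eff_sum[[ki]] <- eff_sum[[ki]] + g[blocks[[ki]]]
    }
  }
  effect_means <- lapply(eff_sum, function(v) v / max(kept, 1L))
  names(effect_means) <- names(random)
  list(draws = draws, effect_means = effect_means)
}
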