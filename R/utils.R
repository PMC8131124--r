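# Small numerical helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (design, founders, fertilization, larvae, sampler, ...) draw from
#' named sub-streams so that adding a stage never perturbs another stage's
#' stream.
#'
#' @param seed Master integer seed.
#' @param stream Character name of the sub-stream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2011 + h * 17 + 1) %% 2147483647L
}

# scaled inverse-chi-square draw: sigma2 ~ ScInvChi2(nu, V)
rinvchisq <- function(n, nu, V) {
  nu * V / stats::rchisq(n, df = nu)
}

# inverse-Wishart draw, density |S|^{nu/2} |G|^{-(nu+p+1)/2} exp(-tr(S G^-1)/2)
rinvwishart <- function(nu, S) {
  W <- stats::rWishart(1L, df = nu, Sigma = solve(S))[, , 1L]
  solve(W)
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass, computed from sorted
#' draws (Chen-Shao window method).
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Interval mass (default 0.95).
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(x[1L], x[1L]))
  k <- max(1L, floor(prob * n))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  j <- which.min(widths)
  c(x[j], x[j + k])
}

#' Posterior mode via kernel density
#'
#' @param x Numeric vector of posterior draws.
#' @return The abscissa of the kernel-density maximum.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) return(x[1L])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Effective sample size of an MCMC chain
#'
#' Uses the initial positive sequence of autocorrelations (Geyer-style
#' truncation at the first negative estimate).
#'
#' @param x Numeric vector (one chain, one parameter).
#' @return Estimated effective number of independent draws.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  lag_max <- min(n - 1L, max(50L, floor(10 * log10(n))))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  ess <- n / (1 + 2 * sum(rho))
  min(max(ess, 1), n)
}

#' Satterthwaite degrees of freedom for a linear combination of variances
#'
#' For an estimated variance `sum(c_i * v_i)` built from independent mean
#' squares `v_i` on `df_i` degrees of freedom, returns the Satterthwaite
#' approximation `(sum c v)^2 / sum((c v)^2 / df)`. With two components
#' `s1^2/n1 + s2^2/n2` this is exactly the Welch-Satterthwaite two-sample
#' formula.
#'
#' @param v Variance components (already scaled, i.e. `c_i * v_i`).
#' @param df Degrees of freedom of each component.
#' @return Approximate degrees of freedom.
#' @export
satterthwaite_df <- function(v, df) {
  stopifnot(length(v) == length(df), all(df > 0))
  sum(v)^2 / sum(v^2 / df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
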