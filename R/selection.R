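# Breeder's-equation and truncation-selection calculations linking
# heritability estimates to selection differentials and culling fractions.

#' Selection differential required for a given response
#'
#' Inverts the breeder's equation `R = h2 * S`: the per-generation selection
#' differential needed to produce response `R` given narrow-sense
#' heritability `h2`.
#'
#' @param R Desired response per generation (um).
#' @param h2 Narrow-sense heritability, in `(0, 1]`.
#' @return Selection differential `S = R / h2` (um).
#' @examples
#' selection_differential(3.4, 0.68)  # 5
#' @export
selection_differential <- function(R, h2) {
  if (any(h2 <= 0)) stop("h2 must be > 0")
  R / h2
}

#' Predicted response to selection
#'
#' Forward breeder's equation `R = h2 * S`; exact inverse of
#' [selection_differential()].
#'
#' @param h2 Narrow-sense heritability.
#' @param S Selection differential (um).
#' @return Response per generation (um).
#' @export
predicted_response <- function(h2, S) {
  h2 * S
}

#' Selection intensity of lower-tail truncation
#'
#' For culling the smallest fraction `q_culled` of a normally distributed
#' phenotype, the mean of the survivors exceeds the population mean by
#' `i = dnorm(z) / (1 - q)` phenotypic SDs, with `z = qnorm(q)`.
#'
#' @param q_culled Culled (lower-tail) fraction, in `[0, 1)`.
#' @return Selection intensity `i` (unitless; `S = i * sigma_p`).
#' @examples
#' truncation_intensity(0.5)   # dnorm(0) / 0.5 = 0.7979
#' truncation_intensity(0.25)  # ~0.4237
#' @export
truncation_intensity <- function(q_culled) {
  if (any(q_culled < 0 | q_culled >= 1)) stop("q_culled must lie in [0, 1)")
  ifelse(q_culled == 0, 0,
         stats::dnorm(stats::qnorm(q_culled)) / (1 - q_culled))
}

#' Culling fraction required to achieve a selection differential
#'
#' Solves `truncation_intensity(q) = S / sigma_p` for the lower-tail culled
#' fraction `q` by bracketed root finding (tolerance 1e-8), under the normal
#' phenotype assumption.
#'
#' @param S Required selection differential (um), `>= 0`.
#' @param sigma_p Phenotypic standard deviation (um), `> 0`.
#' @return Culled fraction `q` in `[0, 1)`.
#' @examples
#' required_culling_fraction(5, sqrt(140.7 / 0.68))  # ~0.198
#' @export
required_culling_fraction <- function(S, sigma_p) {
  stopifnot(S >= 0, sigma_p > 0)
  if (S == 0) return(0)
  i_req <- S / sigma_p
  upper <- 1 - 1e-12
  if (truncation_intensity(upper) < i_req)
    stop("required intensity ", signif(i_req, 4),
         " is unattainable by truncation with q < 1")
  stats::uniroot(function(q) truncation_intensity(q) - i_req,
                 lower = 0, upper = upper, tol = 1e-8)$root
}

#' Empirical selection differential from observed phenotypes
#'
#' Computes `S` directly from a sample: the mean of the phenotypes remaining
#' after deleting the smallest fraction `q_culled`, minus the overall mean.
#' Distribution-free cross-check of the normal-theory route.
#'
#' @param lengths Numeric phenotype vector (um).
#' @param q_culled Culled lower-tail fraction.
#' @return Empirical selection differential (um).
#' @export
empirical_selection_differential <- function(lengths, q_culled) {
  stopifnot(q_culled >= 0, q_culled < 1, length(lengths) > 1)
  if (q_culled == 0) return(0)
  cut <- stats::quantile(lengths, q_culled, type = 1)
  mean(lengths[lengths > cut]) - mean(lengths)
}

#' Selection report
#'
#' Combines the breeder's-equation quantities for a size deficit `R` to be
#' offset per generation: the required selection differential, intensity,
#' and culling fraction. `sigma_p` defaults to `sqrt(Va / h2)` (plug-in of
#' the additive variance and heritability point estimates). If `lengths` is
#' given, an empirical-distribution culling fraction is reported alongside
#' the normal-theory one.
#'
#' @param R Response to offset per generation (um).
#' @param h2 Narrow-sense heritability.
#' @param Va Additive genetic variance (um^2), used for the default
#'   `sigma_p`.
#' @param sigma_p Phenotypic SD (um); overrides `Va` if supplied.
#' @param lengths Optional phenotype vector for the empirical mode.
#' @return List of class `selection_report`: `R, h2, sigma_p, S, i,
#'   q_required, mode` (+ `q_required_empirical` if `lengths` given).
#' @export
selection_report <- function(R, h2, Va = NULL, sigma_p = NULL, lengths = NULL) {
  if (is.null(sigma_p)) {
    if (is.null(Va)) stop("supply either sigma_p or Va")
    sigma_p <- sqrt(Va / h2)
  }
  S <- selection_differential(R, h2)
  q <- required_culling_fraction(S, sigma_p)
  out <- list(R = R, h2 = h2, sigma_p = sigma_p, S = S,
              i = S / sigma_p, q_required = q, mode = "normal-theory")
  if (!is.null(lengths)) {
    qs <- seq(0.001, 0.999, by = 0.001)
    emp <- vapply(qs, function(qq) empirical_selection_differential(lengths, qq),
                  numeric(1))
    k <- which(emp >= S)
    out$q_required_empirical <- if (length(k)) qs[min(k)] else NA_real_
    out$mode <- "normal-theory + empirical"
  }
  class(out) <- "selection_report"
  out
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection report (breeder's equation, lower-tail truncation)\n")
  cat(sprintf("  response to offset R = %.3g um/gen at h2 = %.3g\n", x$R, x$h2))
  cat(sprintf("  selection differential S = %.4g um (i = %.4g at sigma_p = %.4g um)\n",
              x$S, x$i, x$sigma_p))
  cat(sprintf("  required culling fraction q = %.3f (%.1f%% mortality)\n",
              x$q_required, 100 * x$q_required))
  if (!is.null(x$q_required_empirical))
    cat(sprintf("  empirical-distribution q = %.3f\n", x$q_required_empirical))
  invisible(x)
}
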