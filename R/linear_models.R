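# Mixed-model ANOVA machinery for the environmental / transgenerational-
# plasticity tests: REML fits with dam/sire random intercepts, marginal
# (Type-III) F tests with Satterthwaite denominator df, Tukey HSD contrasts
# with percent-difference effect sizes, and the egg-quality test battery.
#
# REML fitting, Satterthwaite df and the studentized-range adjustment are
# delegated to lme4/lmerTest/emmeans; the module defines the analysis
# surface, conventions and reporting.

#' Fit a linear mixed model with random dam/sire intercepts
#'
#' Fixed effects are supplied as a formula; random intercepts as a character
#' vector of grouping columns. Factors are coded sum-to-zero so the marginal
#' (Type-III-style) tests of [anova_table()] are well defined. With
#' `random = NULL` (or when a random term's variance collapses to zero) the
#' fit reduces to ordinary least squares.
#'
#' @param formula Fixed-effect formula, e.g.
#'   `length_um ~ salinity * dam_site + salinity * sire_site`.
#' @param data Data frame (phenotype, survival, or egg-quality table).
#' @param random Character vector of random-intercept columns (default
#'   `c("dam_id", "sire_id")`); `NULL` for none.
#' @return Object of class `lmm_fit` wrapping the underlying fit with
#'   extracted fixed effects, variance components and REML log-likelihood.
#' @export
fit_lmm <- function(formula, data, random = c("dam_id", "sire_id")) {
  vars <- all.vars(formula)
  resp <- vars[1]
  if (!is.numeric(data[[resp]])) stop("response must be numeric")
  fixed_vars <- intersect(vars[-1], names(data))
  contr <- list()
  for (v in fixed_vars) {
    if (!is.numeric(data[[v]])) {
      data[[v]] <- factor(data[[v]])
      if (nlevels(data[[v]]) < 2)
        stop("fixed factor '", v, "' has fewer than 2 levels")
      contr[[v]] <- "contr.sum"
    }
  }
  random <- random[random %in% names(data)]
  if (length(random)) {
    rforms <- paste0("(1 | ", random, ")")
    full <- stats::as.formula(paste(deparse(formula),
                                    paste(rforms, collapse = " + "),
                                    sep = " + "))
    fit <- lmerTest::lmer(full, data = data, REML = TRUE,
                          contrasts = if (length(contr)) contr else NULL,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual",
                                               "residual", vc$grp))
    obj <- list(fit = fit, mixed = TRUE,
                fixef = lme4::fixef(fit), vcov = as.matrix(stats::vcov(fit)),
                varcomp = varcomp, reml_loglik = as.numeric(stats::logLik(fit)))
  } else {
    fit <- stats::lm(formula, data = data,
                     contrasts = if (length(contr)) contr else NULL)
    obj <- list(fit = fit, mixed = FALSE,
                fixef = stats::coef(fit), vcov = stats::vcov(fit),
                varcomp = c(residual = summary(fit)$sigma^2),
                reml_loglik = as.numeric(stats::logLik(fit)))
  }
  obj$formula <- formula
  obj$random <- random
  obj$data <- data
  class(obj) <- "lmm_fit"
  obj
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(if (x$mixed) "REML linear mixed model" else "Linear model (OLS)", "\n")
  cat("  fixed: ", deparse(x$formula), "\n")
  if (length(x$random)) cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  cat("  variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Marginal (Type-III) ANOVA table
#'
#' Per-term F statistics with sum-to-zero contrasts; for mixed fits the
#' denominator df are Satterthwaite approximations, for OLS fits the
#' classical residual df.
#'
#' @param fit An `lmm_fit`.
#' @return `data.frame` with `term, F, df_num, df_den, p`.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (qr(stats::model.matrix(fit$fit))$rank < ncol(stats::model.matrix(fit$fit)))
    stop("rank-deficient fixed-effect design (aliased terms)")
  if (fit$mixed) {
    a <- stats::anova(fit$fit, type = 3, ddf = "Satterthwaite")
    out <- data.frame(term = rownames(a), F = a[["F value"]],
                      df_num = a$NumDF, df_den = a$DenDF,
                      p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
  } else {
    a <- stats::drop1(fit$fit, scope = stats::terms(fit$fit), test = "F")
    a <- a[-1, , drop = FALSE]
    out <- data.frame(term = rownames(a), F = a[["F value"]],
                      df_num = a$Df,
                      df_den = stats::df.residual(fit$fit),
                      p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tukey HSD contrasts with percent-difference effect sizes
#'
#' All pairwise comparisons of the cell means of the named factors,
#' familywise-adjusted via the studentized-range distribution with
#' Satterthwaite df. The percent difference is computed relative to the
#' smaller cell mean ("X% larger" convention) with a delta-method SE.
#'
#' @param fit An `lmm_fit`.
#' @param specs Character vector of factor names defining the cells, e.g.
#'   `c("salinity", "dam_site")`.
#' @return `data.frame` with `contrast, estimate, se, df, t, p_tukey,
#'   pct_diff, pct_se`.
#' @export
tukey_contrasts <- function(fit, specs) {
  stopifnot(inherits(fit, "lmm_fit"))
  counts <- table(interaction(fit$data[specs], drop = FALSE))
  if (any(counts == 0))
    stop("empty design cells: ", paste(names(counts)[counts == 0], collapse = ", "))
  em <- emmeans::emmeans(fit$fit, specs = specs,
                         lmer.df = "satterthwaite",
                         lmerTest.limit = nrow(fit$data) + 1L,
                         data = fit$data)
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  emdf <- as.data.frame(em)
  mu <- emdf$emmean
  labs <- do.call(paste, c(emdf[specs], sep = " "))
  V <- stats::vcov(em)
  pairs_idx <- utils::combn(length(mu), 2)
  pct <- pct_se <- numeric(ncol(pairs_idx))
  for (k in seq_len(ncol(pairs_idx))) {
    i <- pairs_idx[1, k]; j <- pairs_idx[2, k]
    if (mu[i] >= mu[j]) { hi <- i; lo <- j } else { hi <- j; lo <- i }
    pct[k] <- 100 * (mu[hi] - mu[lo]) / mu[lo]
    grad <- numeric(length(mu))
    grad[hi] <- 100 / mu[lo]
    grad[lo] <- -100 * mu[hi] / mu[lo]^2
    pct_se[k] <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  out <- data.frame(contrast = pr$contrast, estimate = pr$estimate,
                    se = pr$SE, df = pr$df, t = pr$t.ratio,
                    p_tukey = pr$p.value, pct_diff = pct, pct_se = pct_se,
                    stringsAsFactors = FALSE)
  attr(out, "cells") <- data.frame(cell = labs, mean = mu)
  out
}

#' Egg-quality test battery
#'
#' Per assay (log-transformed values): (i) the acclimation-site effect on
#' egg quality (ANOVA on dams), and (ii) the slope of family-mean larval
#' length on the dam's egg-quality value with dam and sire random
#' intercepts.
#'
#' @param eggs Egg-quality table (`dam_id, dam_site, assay, value`).
#' @param larvae Phenotype table; `NULL` skips the size-link tests.
#' @return `data.frame` with one row per assay: site-effect F/p and (if
#'   larvae given) size-link slope estimate, SE and p.
#' @export
egg_quality_tests <- function(eggs, larvae = NULL) {
  if (any(eggs$value <= 0)) stop("egg-quality values must be positive (log transform)")
  per_site <- table(unique(eggs[, c("dam_id", "dam_site")])$dam_site)
  if (any(per_site < 2)) stop("need at least 2 dams per site")
  assays <- unique(eggs$assay)
  fam <- NULL
  if (!is.null(larvae)) {
    fam <- stats::aggregate(length_um ~ family_id + dam_id + sire_id,
                            data = larvae, FUN = mean)
  }
  out <- lapply(assays, function(a) {
    d <- eggs[eggs$assay == a, ]
    d$logv <- log(d$value)
    if (stats::sd(d$logv) == 0)
      stop("assay '", a, "' has zero variance on the log scale")
    f1 <- fit_lmm(logv ~ dam_site, d, random = NULL)
    at <- anova_table(f1)
    row <- data.frame(assay = a, site_F = at$F[1], site_p = at$p[1],
                      stringsAsFactors = FALSE)
    if (!is.null(fam)) {
      dd <- merge(fam, d[, c("dam_id", "logv")], by = "dam_id")
      if (nrow(dd) >= 4) {
        f2 <- tryCatch(fit_lmm(length_um ~ logv, dd,
                               random = c("dam_id", "sire_id")),
                       error = function(e) fit_lmm(length_um ~ logv, dd,
                                                   random = NULL))
        ct <- if (f2$mixed) stats::coef(summary(f2$fit)) else
          stats::coef(summary(f2$fit))
        row$slope <- ct["logv", "Estimate"]
        row$slope_se <- ct["logv", "Std. Error"]
        row$slope_p <- ct["logv", ncol(ct)]
      } else {
        row$slope <- row$slope_se <- row$slope_p <- NA_real_
      }
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
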