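# Configuration-driven orchestration of the full workflow on synthetic (or
# user-supplied CSV) data: simulate -> ANOVA/Tukey -> univariate animal
# models per salinity -> bivariate family covariance -> selection report ->
# diagnostics, with all outputs written next to the resolved configuration.

#' Default pipeline configuration
#'
#' @param scale `"tiny"` (4 blocks, 10 larvae/family, short chains; runs in
#'   seconds) or `"paper"` (full 16-block design, production chain lengths).
#' @return A nested list validated by [run_pipeline()]; round-trips to YAML
#'   via `yaml::write_yaml`/`yaml::read_yaml`.
#' @export
default_config <- function(scale = c("tiny", "paper")) {
  scale <- match.arg(scale)
  params <- default_params()
  if (scale == "tiny") params$n_offspring_measured <- 10
  design <- list(n_blocks = if (scale == "tiny") 4 else 16,
                 dams_per_site = 2, sires_per_site = 1,
                 dam_reuse_fraction = if (scale == "tiny") c(0, 0)
                                      else c(0.8125, 0.6875))
  mcmc <- if (scale == "tiny") list(n_iter = 4000, burn_in = 1000, thin = 3)
          else list(n_iter = 1300000, burn_in = 300000, thin = 1000)
  list(scale = scale, params = params, design = design, mcmc = mcmc,
       inputs = NULL,  # optional list(phenotypes=, crosses=) of CSV paths
       selection = list(R = 3.4))
}

.pipe_stage <- function(stage, expr, log) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE))
  cat(sprintf("stage %-12s %8.2fs\n", stage, proc.time()[["elapsed"]] - t0),
      file = log, append = TRUE)
  res
}

#' Run the full analysis pipeline
#'
#' Deterministic given `seed`: simulates (or ingests) the experiment, runs
#' the three-way mixed ANOVA with Tukey contrasts, fits the univariate
#' animal model at each rearing salinity and the bivariate family-mean
#' covariance model, computes the selection report, and writes CSV/JSON
#' outputs, a diagnostics report, PNG diagnostic plots, and the resolved
#' configuration into `outdir`.
#'
#' @param config Configuration from [default_config()] (or a compatible
#'   list, e.g. read back from YAML).
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed.
#' @return Invisibly, a list with all fitted objects and tables.
#' @export
run_pipeline <- function(config = default_config("tiny"), outdir = tempfile("run"),
                         seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outdir, "pipeline.log")
  cat("pipeline run, R ", as.character(getRversion()), "\n", sep = "", file = log)
  params <- config$params
  if (!inherits(params, "generative_params")) class(params) <- "generative_params"
  validate_params(params)
  yaml::write_yaml(list(seed = seed, scale = config$scale,
                        design = config$design, mcmc = config$mcmc,
                        selection = config$selection,
                        params = unclass(params)),
                   file.path(outdir, "config_resolved.yaml"))

  # stage 1: data ------------------------------------------------------------
  sim <- .pipe_stage("simulate", {
    if (!is.null(config$inputs)) {
      phen <- read_phenotypes(config$inputs$phenotypes)
      crosses <- read_crosses(config$inputs$crosses)
      list(crosses = crosses, phenotypes = phen, survival = NULL, eggs = NULL,
           pedigree = pedigree_from_phenotypes(phen))
    } else {
      d <- config$design
      simulate_experiment(params, seed, n_blocks = d$n_blocks,
                          dams_per_site = d$dams_per_site,
                          sires_per_site = d$sires_per_site,
                          dam_reuse_fraction = unlist(d$dam_reuse_fraction))
    }
  }, log)
  if (is.null(sim$phenotypes) || nrow(sim$phenotypes) == 0)
    stop("stage [simulate]: no fertilized families produced any larvae; ",
         "nothing to analyse", call. = FALSE)
  write_table_csv(sim$phenotypes, file.path(outdir, "phenotypes.csv"))
  write_crosses(sim$crosses, file.path(outdir, "crosses.csv"))
  write_pedigree(sim$pedigree, file.path(outdir, "pedigree.csv"))
  if (!is.null(sim$survival))
    write_table_csv(sim$survival, file.path(outdir, "survival.csv"))
  if (!is.null(sim$eggs))
    write_table_csv(sim$eggs, file.path(outdir, "egg_quality.csv"))

  # stage 2: environmental / TGP ANOVAs --------------------------------------
  anovas <- .pipe_stage("anova", {
    fit <- fit_lmm(length_um ~ salinity * dam_site + salinity * sire_site,
                   sim$phenotypes)
    at <- anova_table(fit)
    tk_sal <- tukey_contrasts(fit, "salinity")
    tk_dam <- tukey_contrasts(fit, c("salinity", "dam_site"))
    tk_sire <- tukey_contrasts(fit, c("salinity", "sire_site"))
    surv_fit <- NULL
    if (!is.null(sim$survival) && nrow(sim$survival))
      surv_fit <- tryCatch(
        anova_table(fit_lmm(mortality ~ salinity + dam_site + sire_site,
                            sim$survival, random = NULL)),
        error = function(e) NULL)
    list(fit = fit, table = at, tukey_salinity = tk_sal,
         tukey_dam = tk_dam, tukey_sire = tk_sire, survival_table = surv_fit)
  }, log)
  write_table_csv(anovas$table, file.path(outdir, "anova_length.csv"))
  write_table_csv(anovas$tukey_dam, file.path(outdir, "tukey_dam.csv"))
  write_table_csv(anovas$tukey_sire, file.path(outdir, "tukey_sire.csv"))

  egg_tests <- NULL
  if (!is.null(sim$eggs) && nrow(sim$eggs)) {
    egg_tests <- .pipe_stage("egg_quality",
      egg_quality_tests(sim$eggs, sim$phenotypes), log)
    write_table_csv(egg_tests, file.path(outdir, "egg_quality_tests.csv"))
  }

  # stage 3: univariate animal models per salinity ----------------------------
  mc <- mcmc_settings(config$mcmc$n_iter, config$mcmc$burn_in,
                      config$mcmc$thin, seed = substream_seed(seed, "animal"))
  fits <- .pipe_stage("animal_model", {
    lapply(c(LOW = "LOW", AMBIENT = "AMBIENT"), function(env) {
      animal_model(length_um ~ dam_site + sire_site, sim$phenotypes,
                   salinity = env, mcmc = mc)
    })
  }, log)
  post <- lapply(fits, function(f) {
    s <- summary(f)
    list(parameters = s$parameters, ratios = s$ratios)
  })
  for (env in names(fits)) {
    write_table_csv(as.data.frame(fits[[env]]$draws),
                    file.path(outdir, paste0("posterior_", tolower(env), ".csv")))
    sm <- summary(fits[[env]])$parameters
    js <- lapply(seq_len(nrow(sm)), function(i) list(
      mean = sm$mean[i], mode = sm$mode[i],
      hpd95_low = sm$hpd_low[i], hpd95_high = sm$hpd_high[i], ess = sm$ess[i]))
    names(js) <- sm$parameter
    jsonlite::write_json(js, file.path(outdir, paste0("posterior_", tolower(env), ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  # stage 4: bivariate family covariance --------------------------------------
  bimc <- mcmc_settings(max(4000, config$mcmc$n_iter %/% 10),
                        max(1000, config$mcmc$burn_in %/% 10),
                        max(1, config$mcmc$thin %/% 10),
                        seed = substream_seed(seed, "bivariate"))
  fam <- family_mean_table(sim$phenotypes)
  bi <- .pipe_stage("bivariate", tryCatch(
    fit_bivariate_family_model(fam, mcmc = bimc),
    error = function(e) { warning("bivariate stage skipped: ",
                                  conditionMessage(e)); NULL }), log)

  # Table-1-style layout: variances on the diagonal, family covariance below,
  # family-mean r^2 above
  vr_low <- variance_ratios(fits$LOW); vr_amb <- variance_ratios(fits$AMBIENT)
  va_low <- posterior_mode(fits$LOW$draws[, "sigma2_a"])
  va_amb <- posterior_mode(fits$AMBIENT$draws[, "sigma2_a"])
  both <- stats::complete.cases(fam[, c("mean_low", "mean_ambient")])
  r2 <- if (sum(both) > 2)
    stats::cor(fam$mean_low[both], fam$mean_ambient[both])^2 else NA_real_
  gcov <- if (!is.null(bi)) posterior_mode(bi$draws[, "G12"]) else NA_real_
  table1 <- matrix(c(va_low, gcov, r2, va_amb), 2, 2,
                   dimnames = list(c("8 psu", "15 psu"), c("8 psu", "15 psu")))
  write_table_csv(as.data.frame(table1), file.path(outdir, "table1_layout.csv"))

  # stage 5: selection ---------------------------------------------------------
  sel <- .pipe_stage("selection", {
    h2_mode <- vr_low["h2", "mode"]
    selection_report(R = config$selection$R, h2 = h2_mode, Va = va_low,
                     lengths = sim$phenotypes$length_um[
                       sim$phenotypes$salinity == "LOW"])
  }, log)
  jsonlite::write_json(unclass(sel)[c("R", "h2", "sigma_p", "S", "i",
                                      "q_required", "mode")],
                       file.path(outdir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 6: diagnostics --------------------------------------------------------
  diag_rep <- .pipe_stage("diagnostics", {
    lapply(fits, mcmc_diagnostics, ess_threshold = min(200, nrow(fits$LOW$draws) / 2))
  }, log)
  con <- file(file.path(outdir, "diagnostics.txt"), "w")
  for (env in names(diag_rep)) {
    cat("== ", env, " ==\n", sep = "", file = con)
    utils::capture.output(print(diag_rep[[env]]), file = con, append = TRUE)
  }
  close(con)
  grDevices::png(file.path(outdir, "trace_plots.png"), width = 900, height = 700)
  plot(fits$LOW)
  grDevices::dev.off()
  grDevices::png(file.path(outdir, "residual_vs_block.png"), width = 700, height = 500)
  .residual_block_plot(anovas$fit, sim)
  grDevices::dev.off()

  invisible(list(sim = sim, anovas = anovas, egg_tests = egg_tests,
                 animal_fits = fits, bivariate = bi, table1 = table1,
                 selection = sel, diagnostics = diag_rep, outdir = outdir))
}

# residual-vs-block diagnostic supporting the choice not to model block as a
# random effect
.residual_block_plot <- function(fit, sim) {
  res <- stats::resid(fit$fit)
  blk <- sim$crosses$block[match(fit$data$family_id, sim$crosses$family)]
  if (all(is.na(blk))) blk <- rep(1, length(res))
  graphics::boxplot(res ~ factor(blk), xlab = "block", ylab = "residual (um)",
                    main = "model residuals by experimental block")
  graphics::abline(h = 0, lty = 2)
}

#' Write fixture file sets
#'
#' Generates a complete synthetic experiment and writes its tables as CSV:
#' `tiny` (4 blocks, 10 larvae per family; seconds-fast) or `paper_scale`
#' (full 16-block configuration whose per-treatment phenotype totals land
#' near 1248 / 1379 measured larvae).
#'
#' @param size `"tiny"` or `"paper_scale"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, the list of written paths.
#' @export
make_fixtures <- function(size = c("tiny", "paper_scale"), seed = 1,
                          dir = tempfile("fixtures")) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- default_config(if (size == "tiny") "tiny" else "paper")
  sim <- simulate_experiment(cfg$params, seed, n_blocks = cfg$design$n_blocks,
                             dams_per_site = cfg$design$dams_per_site,
                             sires_per_site = cfg$design$sires_per_site,
                             dam_reuse_fraction = unlist(cfg$design$dam_reuse_fraction))
  paths <- list(
    crosses = write_crosses(sim$crosses, file.path(dir, "crosses.csv")),
    phenotypes = write_table_csv(sim$phenotypes, file.path(dir, "phenotypes.csv")),
    survival = write_table_csv(sim$survival, file.path(dir, "survival.csv")),
    eggs = write_table_csv(sim$eggs, file.path(dir, "egg_quality.csv")),
    pedigree = write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv")),
    params = write_params(cfg$params, file.path(dir, "params.yaml")))
  invisible(paths)
}
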