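# Synthetic-data generator: founder breeding values, fertilization outcomes,
# larval phenotypes, family survival, and egg-quality assays, all as pure
# functions of (parameters, seed).

.low_sq <- function(x) as.numeric(x == "LOW") - 0.5  # centered site coding

# fixed-effect surface: treatment + parental acclimation + interactions
.fixed_effect <- function(p, salinity, dam_site, sire_site) {
  low <- as.numeric(salinity == "LOW")
  dl <- .low_sq(dam_site)
  sl <- .low_sq(sire_site)
  p$beta_salinity * low +
    p$beta_dam_acclim * dl + p$beta_sire_acclim * sl +
    p$beta_dam_x_salinity * low * dl + p$beta_sire_x_salinity * low * sl
}

# PSD square root (handles singular covariance, e.g. zero variance or r = 1)
.psd_sqrt <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(G)) %*% t(e$vectors)
}

#' Simulate founder breeding values and maternal effects
#'
#' Founder additive genetic values for larval size are drawn i.i.d. from a
#' bivariate normal across the two rearing environments with covariance
#' [genetic_covariance_matrix()]; dam maternal effects use a single
#' standard-normal dam deviate scaled by the per-environment maternal SD.
#' There is no genetic difference between acclimation sites (all parents
#' share one hatchery origin).
#'
#' @param crosses Cross table from [ncii_cross_table()].
#' @param params Generative parameters (see [default_params()]).
#' @param seed Integer seed.
#' @return A `data.frame` with one row per founder: `id, sex, site,
#'   bv_low, bv_ambient, mat_low, mat_ambient` (maternal columns are 0 for
#'   sires).
#' @export
simulate_founders <- function(crosses, params, seed = 1) {
  validate_params(params)
  set.seed(substream_seed(seed, "founders"))
  dams <- unique(crosses[, c("dam", "dam_site")])
  sires <- unique(crosses[, c("sire", "sire_site")])
  ids <- c(sires$sire, dams$dam)
  n <- length(ids)
  G <- genetic_covariance_matrix(params)
  bv <- matrix(rnorm(2 * n), n, 2) %*% .psd_sqrt(G)
  z <- rnorm(n)
  is_dam <- c(rep(FALSE, nrow(sires)), rep(TRUE, nrow(dams)))
  data.frame(
    id = ids,
    sex = ifelse(is_dam, "dam", "sire"),
    site = c(sires$sire_site, dams$dam_site),
    bv_low = bv[, 1], bv_ambient = bv[, 2],
    mat_low = ifelse(is_dam, z * sqrt(params$sigma2_m$low), 0),
    mat_ambient = ifelse(is_dam, z * sqrt(params$sigma2_m$ambient), 0),
    stringsAsFactors = FALSE)
}

#' Simulate fertilization success of planned crosses
#'
#' Independent Bernoulli(1 - failure rate) per cross; successful crosses are
#' assigned family ids in row order.
#'
#' @inheritParams simulate_founders
#' @return The cross table with `fertilized` and `family` filled in.
#' @export
simulate_fertilization <- function(crosses, params, seed = 1) {
  set.seed(substream_seed(seed, "fertilization"))
  crosses$fertilized <- runif(nrow(crosses)) >= params$fertilization_failure_rate
  crosses$family <- NA_character_
  k <- which(crosses$fertilized)
  crosses$family[k] <- sprintf("FAM%03d", seq_along(k))
  crosses
}

#' Simulate measured larval phenotypes
#'
#' Each fertilized family is split into both rearing salinities. An
#' offspring's breeding value is midparent plus a bivariate Mendelian
#' sampling deviation with covariance G/2 (non-inbred, unrelated founders);
#' its length is `mu + fixed effects + breeding value + dam maternal effect +
#' residual`, with non-positive lengths resampled. Per family and treatment,
#' the number of measured larvae is `Binomial(n_offspring_measured,
#' measure_rate)` and the family-treatment combination is retained with
#' probability `family_keep_prob` (emulating losses before measurement).
#'
#' @param crosses Cross table after [simulate_fertilization()].
#' @param founders Founder effects from [simulate_founders()].
#' @param params Generative parameters.
#' @param seed Integer seed.
#' @param environments Rearing treatments to generate (default both).
#' @return Phenotype `data.frame`: `larva_id, family_id, dam_id, sire_id,
#'   dam_site, sire_site, salinity, length_um`.
#' @export
simulate_larvae <- function(crosses, founders, params, seed = 1,
                            environments = c("LOW", "AMBIENT")) {
  validate_params(params)
  fert <- crosses[which(crosses$fertilized), , drop = FALSE]
  if (nrow(fert) == 0)
    return(data.frame(larva_id = character(0), family_id = character(0),
                      dam_id = character(0), sire_id = character(0),
                      dam_site = character(0), sire_site = character(0),
                      salinity = character(0), length_um = numeric(0)))
  miss <- setdiff(unique(c(fert$dam, fert$sire)), founders$id)
  if (length(miss))
    stop("founder effects missing for parent(s): ", paste(head(miss), collapse = ", "))
  set.seed(substream_seed(seed, "larvae"))
  rownames(founders) <- founders$id
  Lg <- .psd_sqrt(genetic_covariance_matrix(params) / 2)
  ve <- c(LOW = params$sigma2_e$low, AMBIENT = params$sigma2_e$ambient)
  out <- vector("list", nrow(fert) * length(environments))
  k <- 0L
  for (r in seq_len(nrow(fert))) {
    cr <- fert[r, ]
    mid <- (unlist(founders[cr$sire, c("bv_low", "bv_ambient")]) +
            unlist(founders[cr$dam, c("bv_low", "bv_ambient")])) / 2
    mat <- unlist(founders[cr$dam, c("mat_low", "mat_ambient")])
    for (env in environments) {
      k <- k + 1L
      if (runif(1) > params$family_keep_prob) next
      rate <- if (env == "LOW") params$measure_rate$low else params$measure_rate$ambient
      n <- rbinom(1L, params$n_offspring_measured, rate)
      if (n == 0L) next
      bv <- matrix(rnorm(2 * n), n, 2) %*% Lg
      bv[, 1] <- bv[, 1] + mid[1]; bv[, 2] <- bv[, 2] + mid[2]
      env_col <- if (env == "LOW") 1L else 2L
      mu_i <- params$mu +
        .fixed_effect(params, env, cr$dam_site, cr$sire_site) +
        bv[, env_col] + mat[env_col]
      len <- mu_i + rnorm(n, 0, sqrt(ve[[env]]))
      bad <- which(len <= 0)
      while (length(bad)) {  # truncation by resampling keeps the density smooth
        len[bad] <- mu_i[bad] + rnorm(length(bad), 0, sqrt(ve[[env]]))
        bad <- bad[len[bad] <= 0]
      }
      out[[k]] <- data.frame(
        larva_id = sprintf("%s_%s_%03d", cr$family, substr(env, 1, 1), seq_len(n)),
        family_id = cr$family, dam_id = cr$dam, sire_id = cr$sire,
        dam_site = cr$dam_site, sire_site = cr$sire_site,
        salinity = env, length_um = len, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate family-level larval survival
#'
#' Per family and treatment, a mortality probability is drawn on the logit
#' scale around `logit(mortality_mean)` with SD `mortality_dispersion`, and
#' deaths are binomial. No treatment or parental-site effect is injected by
#' default.
#'
#' @param crosses Cross table after [simulate_fertilization()].
#' @param params Generative parameters.
#' @param seed Integer seed.
#' @return `data.frame`: `family_id, dam_site, sire_site, salinity, n_total,
#'   n_dead, mortality`.
#' @export
simulate_survival <- function(crosses, params, seed = 1) {
  set.seed(substream_seed(seed, "survival"))
  fert <- crosses[which(crosses$fertilized), , drop = FALSE]
  envs <- c("LOW", "AMBIENT")
  g <- expand.grid(r = seq_len(nrow(fert)), env = envs, stringsAsFactors = FALSE)
  m <- params$mortality_mean
  n_tot <- params$survival_n
  p <- if (m <= 0) rep(0, nrow(g))
       else if (m >= 1) rep(1, nrow(g))
       else plogis(rnorm(nrow(g), qlogis(m), params$mortality_dispersion))
  dead <- rbinom(nrow(g), n_tot, p)
  data.frame(family_id = fert$family[g$r],
             dam_site = fert$dam_site[g$r], sire_site = fert$sire_site[g$r],
             salinity = g$env, n_total = n_tot, n_dead = dead,
             mortality = dead / n_tot, stringsAsFactors = FALSE)
}

#' Simulate egg-quality assays
#'
#' Log-normal values per dam per assay (protein and five lipid classes).
#' By default there is no acclimation-site effect and no link to larval
#' size; `egg_site_effect` injects a log-scale site shift for power studies.
#'
#' @param dams `data.frame` with columns `dam` (or `id`) and `dam_site` (or
#'   `site`), one row per assayed dam.
#' @param params Generative parameters.
#' @param seed Integer seed.
#' @return `data.frame`: `dam_id, dam_site, assay, value`.
#' @export
simulate_egg_quality <- function(dams, params, seed = 1) {
  set.seed(substream_seed(seed, "egg_quality"))
  id <- dams[[if ("dam" %in% names(dams)) "dam" else "id"]]
  site <- dams[[if ("dam_site" %in% names(dams)) "dam_site" else "site"]]
  assays <- names(params$egg_quality_means)
  g <- expand.grid(d = seq_along(id), assay = assays, stringsAsFactors = FALSE)
  mu <- unlist(params$egg_quality_means)[g$assay] +
    params$egg_site_effect * (site[g$d] == "LOW")
  sd_ <- unlist(params$egg_quality_sds)[g$assay]
  data.frame(dam_id = id[g$d], dam_site = site[g$d], assay = g$assay,
             value = exp(rnorm(nrow(g), mu, sd_)), stringsAsFactors = FALSE)
}

#' Simulate a complete experiment
#'
#' Chains design, fertilization, founder effects, larval phenotypes,
#' survival, and egg quality with one master seed. Defaults reproduce the
#' full 16-block design with dam reuse tuned to 19 (low-site) and 21
#' (medium-site) distinct dams.
#'
#' @param params Generative parameters.
#' @param seed Master integer seed.
#' @param n_blocks,dams_per_site,sires_per_site,dam_reuse_fraction Passed to
#'   [ncii_cross_table()].
#' @param n_egg_dams_per_site Dams assayed for egg quality per site.
#' @return A list with `crosses, founders, phenotypes, survival, eggs,
#'   pedigree`.
#' @export
simulate_experiment <- function(params = default_params(), seed = 1,
                                n_blocks = 16, dams_per_site = 2,
                                sires_per_site = 1,
                                dam_reuse_fraction = c(0.8125, 0.6875),
                                n_egg_dams_per_site = 15) {
  crosses <- ncii_cross_table(n_blocks, dams_per_site, sires_per_site,
                              dam_reuse_fraction, seed = seed)
  crosses <- simulate_fertilization(crosses, params, seed)
  founders <- simulate_founders(crosses, params, seed)
  phen <- simulate_larvae(crosses, founders, params, seed)
  surv <- simulate_survival(crosses, params, seed)
  dams <- unique(data.frame(dam = crosses$dam, dam_site = crosses$dam_site,
                            stringsAsFactors = FALSE))
  set.seed(substream_seed(seed, "egg_dams"))
  pick <- unlist(lapply(split(seq_len(nrow(dams)), dams$dam_site), function(i)
    if (length(i) > n_egg_dams_per_site) sort(sample(i, n_egg_dams_per_site)) else i))
  eggs <- simulate_egg_quality(dams[pick, ], params, seed)
  ped <- if (nrow(phen)) pedigree_from_phenotypes(phen) else NULL
  list(crosses = crosses, founders = founders, phenotypes = phen,
       survival = surv, eggs = eggs, pedigree = ped)
}

#' Construct a fertilized NC II sub-design with target parent counts
#'
#' Samples fertilized crosses from a fresh NC II design until the realized
#' numbers of distinct sires and dams match the targets (the realized
#' experiment's unbalanced outcome of fertilization failure), used for
#' parameter-recovery simulations.
#'
#' @param n_sires,n_dams,n_families Target distinct sires, distinct dams,
#'   and fertilized families.
#' @param seed Integer seed.
#' @param max_tries Resampling attempts before accepting the closest match.
#' @return A cross table with `fertilized`/`family` set for the sampled
#'   families.
#' @export
recovery_design <- function(n_sires, n_dams, n_families, seed = 1,
                            max_tries = 500) {
  n_blocks <- ceiling(n_sires / 2)
  crosses <- ncii_cross_table(n_blocks = n_blocks, dams_per_site = 2,
                              sires_per_site = 1, dam_reuse_fraction = 0,
                              seed = seed)
  if (n_families > nrow(crosses)) stop("design too small for requested families")
  set.seed(substream_seed(seed, "recovery_design"))
  best <- NULL; best_score <- Inf
  for (t in seq_len(max_tries)) {
    k <- sample(nrow(crosses), n_families)
    score <- abs(length(unique(crosses$sire[k])) - n_sires) +
             abs(length(unique(crosses$dam[k])) - n_dams)
    if (score < best_score) { best <- k; best_score <- score }
    if (best_score == 0) break
  }
  crosses$fertilized <- FALSE
  crosses$fertilized[best] <- TRUE
  crosses$family <- NA_character_
  crosses$family[sort(best)] <- sprintf("FAM%03d", seq_along(best))
  crosses
}

#' Simulate a single-environment parameter-recovery dataset
#'
#' Generates exactly `n_per_family` measured larvae per family in one
#' rearing environment from a [recovery_design()], with no measurement
#' losses, for animal-model parameter recovery.
#'
#' @param environment `"LOW"` or `"AMBIENT"`.
#' @param n_sires,n_dams,n_families Realized design targets.
#' @param n_per_family Measured larvae per family.
#' @param params Generative parameters.
#' @param seed Integer seed.
#' @return List with `phenotypes`, `pedigree`, `crosses`, `founders`.
#' @export
simulate_recovery_dataset <- function(environment = c("LOW", "AMBIENT"),
                                      n_sires = 12, n_dams = 21,
                                      n_families = 27, n_per_family = 50,
                                      params = default_params(), seed = 1) {
  environment <- match.arg(environment)
  p <- params
  p$family_keep_prob <- 1
  p$measure_rate <- list(low = 1, ambient = 1)
  p$n_offspring_measured <- n_per_family
  crosses <- recovery_design(n_sires, n_dams, n_families, seed = seed)
  founders <- simulate_founders(crosses, p, seed)
  phen <- simulate_larvae(crosses, founders, p, seed, environments = environment)
  list(phenotypes = phen, pedigree = pedigree_from_phenotypes(phen),
       crosses = crosses, founders = founders)
}

#' Family-mean table across rearing environments
#'
#' @param phenotypes Phenotype table.
#' @return `data.frame` with one row per family: `family, dam, sire,
#'   mean_low, mean_ambient, n_low, n_ambient` (NA means where a family has
#'   no larvae in that environment).
#' @export
family_mean_table <- function(phenotypes) {
  sp <- split(phenotypes, phenotypes$family_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    lo <- d$length_um[d$salinity == "LOW"]
    am <- d$length_um[d$salinity == "AMBIENT"]
    data.frame(family = d$family_id[1], dam = d$dam_id[1], sire = d$sire_id[1],
               mean_low = if (length(lo)) mean(lo) else NA_real_,
               mean_ambient = if (length(am)) mean(am) else NA_real_,
               n_low = length(lo), n_ambient = length(am),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Family-level additive relationship matrix
#'
#' Families are pseudo-individuals whose "parents" are their sire and dam,
#' so half-sib families (one shared parent) get relationship 0.25.
#'
#' @param families `data.frame` with columns `family, dam, sire`.
#' @return Dense symmetric matrix indexed by family id.
#' @export
family_relationship_matrix <- function(families) {
  parents <- unique(c(families$sire, families$dam))
  ped <- data.frame(
    id = c(parents, families$family),
    sire = c(rep(NA_character_, length(parents)), families$sire),
    dam = c(rep(NA_character_, length(parents)), families$dam),
    generation = c(rep("founder", length(parents)),
                   rep("offspring", nrow(families))),
    site = NA_character_, sex = NA_character_, stringsAsFactors = FALSE)
  class(ped) <- c("oyster_pedigree", "data.frame")
  A <- relationship_matrix(ped)
  A[families$family, families$family, drop = FALSE]
}

#' Simulate family-mean sizes in both environments
#'
#' Family-level genetic effects are drawn from `N(0, G (x) A_fam)` where
#' `A_fam` is the family relationship matrix of the supplied design, plus
#' independent per-environment residual noise, emulating the family-mean
#' data the bivariate covariance model consumes.
#'
#' @param crosses A fertilized cross table (e.g. [recovery_design()]).
#' @param G 2x2 genetic covariance matrix (low, ambient).
#' @param resid Length-2 residual variances `c(low, ambient)`.
#' @param mu Length-2 environment means `c(low, ambient)`.
#' @param seed Integer seed.
#' @param missing_prob Probability a family lacks data in an environment.
#' @return `data.frame` as from [family_mean_table()].
#' @export
simulate_family_means <- function(crosses, G = genetic_covariance_matrix(default_params()),
                                  resid = c(23.6, 30.3),
                                  mu = c(72.16, 75.56), seed = 1,
                                  missing_prob = 0) {
  fert <- crosses[which(crosses$fertilized), , drop = FALSE]
  fam <- data.frame(family = fert$family, dam = fert$dam, sire = fert$sire,
                    stringsAsFactors = FALSE)
  A <- family_relationship_matrix(fam)
  set.seed(substream_seed(seed, "family_means"))
  LA <- chol(A)            # upper-triangular, t(LA) %*% LA = A
  LG <- .psd_sqrt(G)
  g <- t(LA) %*% matrix(rnorm(2 * nrow(fam)), nrow(fam), 2) %*% LG
  y <- sweep(g, 2, mu, "+") +
    cbind(rnorm(nrow(fam), 0, sqrt(resid[1])), rnorm(nrow(fam), 0, sqrt(resid[2])))
  if (missing_prob > 0) {
    drop_ <- matrix(runif(2 * nrow(fam)) < missing_prob, nrow(fam), 2)
    drop_[drop_[, 1] & drop_[, 2], 2] <- FALSE  # keep at least one environment
    y[drop_] <- NA
  }
  data.frame(family = fam$family, dam = fam$dam, sire = fam$sire,
             mean_low = y[, 1], mean_ambient = y[, 2],
             n_low = as.integer(!is.na(y[, 1])),
             n_ambient = as.integer(!is.na(y[, 2])), stringsAsFactors = FALSE)
}

#' Write phenotype/survival/egg tables to CSV
#' @param x Table to write.
#' @param path File path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#' @param path File path.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
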