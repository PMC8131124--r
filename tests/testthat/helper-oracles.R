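# Independent oracles and small fixture builders used across tests.

# Recursive kinship coefficient oracle: f(i, j) with memoization.
# A_ij = 2 * f(i, j); independent of the tabular-method implementation.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else if (i < j) {
      # j later in pedigree: recurse through j's parents
      0.5 * (f(i, si[j]) + f(i, di[j]))
    } else {
      0.5 * (f(j, si[i]) + f(j, di[i]))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  2 * K
}

# Random valid pedigree: n_founders unrelated founders, then offspring whose
# parents are drawn from earlier individuals (loops and inbreeding allowed).
random_pedigree <- function(n_total, n_founders = max(2, ceiling(n_total / 3)),
                            seed = 1) {
  set.seed(seed)
  id <- sprintf("I%02d", seq_len(n_total))
  sire <- dam <- rep(NA_character_, n_total)
  for (i in (n_founders + 1):n_total) {
    pick <- sample(seq_len(i - 1), 2, replace = FALSE)
    sire[i] <- id[pick[1]]; dam[i] <- id[pick[2]]
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = ifelse(is.na(sire), "founder", "offspring"),
                    site = NA_character_, sex = NA_character_,
                    stringsAsFactors = FALSE)
  class(ped) <- c("oyster_pedigree", "data.frame")
  ped
}

# A five-individual pedigree containing a full-sib mating (inbred offspring).
fullsib_mating_pedigree <- function() {
  ped <- data.frame(
    id = c("A", "B", "C", "D", "E"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "D"),
    generation = c("founder", "founder", "offspring", "offspring", "offspring"),
    site = NA_character_, sex = NA_character_, stringsAsFactors = FALSE)
  class(ped) <- c("oyster_pedigree", "data.frame")
  ped
}

# Small single-environment dataset for animal-model tests.
small_recovery <- function(seed = 1, n_sires = 8, n_dams = 14, n_families = 16,
                           n_per_family = 10, env = "LOW") {
  simulate_recovery_dataset(env, n_sires, n_dams, n_families, n_per_family,
                            seed = seed)
}

# Calibrated parameters without genotype-by-environment variation: breeding
# values identical across rearing environments (r_g = 1, equal variances),
# so family-level G x E noise does not swamp fixed-effect contrasts. Used to
# test the ANOVA machinery's power in isolation.
no_gxe_params <- function() {
  p <- default_params()
  p$sigma2_a <- list(low = 140.7, ambient = 140.7)
  p$gcov <- 140.7
  p
}

# Quick zero-genetics parameter set (keeps fixed-effect surface).
null_variance_params <- function(sigma2_e = 25) {
  p <- default_params()
  p$sigma2_a <- list(low = 0, ambient = 0)
  p$sigma2_m <- list(low = 0, ambient = 0)
  p$sigma2_e <- list(low = sigma2_e, ambient = sigma2_e)
  p$gcov <- 0
  p
}
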