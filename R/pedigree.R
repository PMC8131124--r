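# North Carolina II cross design and pedigree machinery: cross tables,
# two-generation pedigrees, the additive relationship matrix A (tabular
# method) and its sparse inverse (Henderson's rules with inbreeding).

.SITES <- c("LOW", "MEDIUM")

#' Build a modified North Carolina II cross table
#'
#' Constructs the planned matings of a blocked NC II design: within each
#' block, every dam is crossed with every sire. Sires are never reused across
#' blocks; a configurable fraction of dam slots is filled by dams reused from
#' an earlier block, so a reused dam (crossed with the two sires of each of
#' her two blocks) meets four distinct sires in total. Parents come from two
#' acclimation sites (`LOW` and `MEDIUM` salinity); the canonical
#' configuration has one sire and two dams per site per block.
#'
#' @param n_blocks Number of experimental blocks (default 16).
#' @param dams_per_site Dams per acclimation site per block (default 2).
#' @param sires_per_site Sires per acclimation site per block (default 1).
#' @param dam_reuse_fraction Fraction of a site's dam slots occupied by dams
#'   appearing in two blocks (both appearances counted). May be a single
#'   value or a length-2 vector named after the sites. 0 means every slot
#'   gets a fresh dam.
#' @param seed Integer seed controlling which blocks share dams.
#' @return A `data.frame` of planned crosses with columns
#'   `block, dam, sire, dam_site, sire_site, fertilized, family`
#'   (`fertilized`/`family` are `NA` until [simulate_fertilization()] runs).
#' @examples
#' crosses <- ncii_cross_table(n_blocks = 2, seed = 1)
#' nrow(crosses)  # 2 blocks x 4 dams x 2 sires = 16
#' @export
ncii_cross_table <- function(n_blocks = 16, dams_per_site = 2, sires_per_site = 1,
                             dam_reuse_fraction = 0, seed = 1) {
  stopifnot(n_blocks >= 1, dams_per_site >= 1, sires_per_site >= 1)
  if (length(dam_reuse_fraction) == 1L)
    dam_reuse_fraction <- rep(dam_reuse_fraction, 2L)
  dam_reuse_fraction <- unname(dam_reuse_fraction)
  if (any(dam_reuse_fraction < 0 | dam_reuse_fraction > 1))
    stop("dam_reuse_fraction must lie in [0, 1]")
  if (any(dam_reuse_fraction > 0) && n_blocks < 2L)
    stop("dam reuse requires at least two blocks")

  set.seed(substream_seed(seed, "ncii_design"))

  # sires: fresh every block
  sire_ids <- list()
  for (s in seq_along(.SITES)) {
    n <- n_blocks * sires_per_site
    sire_ids[[s]] <- sprintf("S_%s_%02d", substr(.SITES[s], 1, 3), seq_len(n))
  }

  # dams: fill a blocks x slots grid per site, then merge slots for reuse
  dam_grid <- list()
  for (s in seq_along(.SITES)) {
    slots <- n_blocks * dams_per_site
    n_reused <- floor(dam_reuse_fraction[s] * slots / 2)
    grid <- matrix(sprintf("D_%s_%02d", substr(.SITES[s], 1, 3), seq_len(slots)),
                   nrow = n_blocks, byrow = TRUE)
    if (n_reused > 0) {
      # each merge replaces one slot in a later block with a dam from an
      # earlier block, keeping every dam in at most two blocks
      used_twice <- character(0)
      for (k in seq_len(n_reused)) {
        for (attempt in 1:100) {
          b2 <- sample(2:n_blocks, 1L)
          j2 <- sample(seq_len(dams_per_site), 1L)
          cand <- grid[b2, j2]
          if (cand %in% used_twice) next
          b1 <- sample(seq_len(b2 - 1L), 1L)
          donor <- setdiff(grid[b1, ], c(grid[b2, ], used_twice))
          if (!length(donor)) next
          donor <- sample(donor, 1L)
          used_twice <- c(used_twice, donor)
          grid[grid == cand] <- donor
          break
        }
      }
    }
    dam_grid[[s]] <- grid
  }

  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    dams  <- character(0); dsite <- character(0)
    sires <- character(0); ssite <- character(0)
    for (s in seq_along(.SITES)) {
      dams  <- c(dams, dam_grid[[s]][b, ])
      dsite <- c(dsite, rep(.SITES[s], dams_per_site))
      idx <- ((b - 1L) * sires_per_site + 1L):(b * sires_per_site)
      sires <- c(sires, sire_ids[[s]][idx])
      ssite <- c(ssite, rep(.SITES[s], sires_per_site))
    }
    g <- expand.grid(di = seq_along(dams), si = seq_along(sires))
    rows[[b]] <- data.frame(
      block = b,
      dam = dams[g$di], sire = sires[g$si],
      dam_site = dsite[g$di], sire_site = ssite[g$si],
      fertilized = NA, family = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dup <- duplicated(out[, c("block", "dam", "sire")])
  if (any(dup)) stop("internal error: duplicate (block, dam, sire) cross")
  out
}

#' Materialize a two-generation pedigree from a cross table
#'
#' Founders (all dams and sires) come first with unknown parents, followed by
#' `offspring_per_family` offspring for every fertilized cross. If the cross
#' table has not been through [simulate_fertilization()] (all `fertilized`
#' `NA`), every cross is treated as fertilized and given a family id.
#'
#' @param crosses Cross table from [ncii_cross_table()].
#' @param offspring_per_family Offspring per fertilized cross.
#' @return A `data.frame` of class `oyster_pedigree` with columns
#'   `id, sire, dam, generation, site, sex` (parents `NA` for founders),
#'   ordered parents-before-offspring.
#' @export
pedigree_from_crosses <- function(crosses, offspring_per_family) {
  stopifnot(is.data.frame(crosses), offspring_per_family >= 0)
  if (all(is.na(crosses$fertilized))) {
    crosses$fertilized <- TRUE
    crosses$family <- sprintf("FAM%03d", seq_len(nrow(crosses)))
  }
  dams <- unique(crosses[, c("dam", "dam_site")])
  sires <- unique(crosses[, c("sire", "sire_site")])
  founders <- data.frame(
    id = c(sires$sire, dams$dam),
    sire = NA_character_, dam = NA_character_,
    generation = "founder",
    site = c(sires$sire_site, dams$dam_site),
    sex = c(rep("sire", nrow(sires)), rep("dam", nrow(dams))),
    stringsAsFactors = FALSE)
  fert <- crosses[which(crosses$fertilized), , drop = FALSE]
  off <- NULL
  if (nrow(fert) > 0 && offspring_per_family > 0) {
    off <- data.frame(
      id = as.vector(t(outer(fert$family, seq_len(offspring_per_family),
                             function(f, k) sprintf("%s_%03d", f, k)))),
      sire = rep(fert$sire, each = offspring_per_family),
      dam = rep(fert$dam, each = offspring_per_family),
      generation = "offspring", site = NA_character_, sex = NA_character_,
      stringsAsFactors = FALSE)
  }
  ped <- rbind(founders, off)
  rownames(ped) <- NULL
  class(ped) <- c("oyster_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Build a pedigree covering the individuals of a phenotype table
#'
#' Founders are the distinct dams and sires referenced by the phenotypes;
#' each measured larva becomes one offspring entry.
#'
#' @param phenotypes Phenotype table (see [simulate_larvae()]).
#' @return An `oyster_pedigree`.
#' @export
pedigree_from_phenotypes <- function(phenotypes) {
  stopifnot(all(c("larva_id", "dam_id", "sire_id") %in% names(phenotypes)))
  phenotypes <- phenotypes[!duplicated(phenotypes$larva_id), , drop = FALSE]
  dams <- unique(phenotypes[, c("dam_id", "dam_site")])
  sires <- unique(phenotypes[, c("sire_id", "sire_site")])
  founders <- data.frame(
    id = c(sires$sire_id, dams$dam_id),
    sire = NA_character_, dam = NA_character_,
    generation = "founder",
    site = c(sires$sire_site, dams$dam_site),
    sex = c(rep("sire", nrow(sires)), rep("dam", nrow(dams))),
    stringsAsFactors = FALSE)
  off <- data.frame(
    id = phenotypes$larva_id, sire = phenotypes$sire_id, dam = phenotypes$dam_id,
    generation = "offspring", site = NA_character_, sex = NA_character_,
    stringsAsFactors = FALSE)
  ped <- rbind(founders, off)
  rownames(ped) <- NULL
  class(ped) <- c("oyster_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, parents-precede-offspring ordering, that founders
#' have both parents unknown, and that non-founders have both parents in the
#' pedigree.
#'
#' @param ped Pedigree `data.frame` with columns `id, sire, dam`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("pedigree ids are not unique")
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(known & !(p %in% ped$id)))
      stop("pedigree references unknown ", col, " id(s): ",
           paste(head(setdiff(p[known], ped$id)), collapse = ", "))
    if (any(pos[p[known]] >= pos[known]))
      stop("pedigree is not ordered parents-before-offspring (", col, ")")
  }
  half <- xor(is.na(ped$sire), is.na(ped$dam))
  # one known parent is tolerated structurally (A-matrix handles it), but the
  # NC II constructors never produce it
  invisible(TRUE)
}

#' Additive relationship matrix by the tabular method
#'
#' `A[i,i] = 1 + A[sire(i), dam(i)]/2` and
#' `A[i,j] = (A[j, sire(i)] + A[j, dam(i)])/2` for `j` earlier in the
#' pedigree; founders are unrelated and non-inbred.
#'
#' @param ped An ordered pedigree (see [validate_pedigree()]).
#' @return A dense symmetric numeric matrix with ids as dimnames.
#' @export
relationship_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped An ordered pedigree.
#' @return Named numeric vector `F = diag(A) - 1`.
#' @export
inbreeding <- function(ped) {
  diag(relationship_matrix(ped)) - 1
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembled directly by Henderson's rules without inverting A: each
#' individual contributes `alpha = 1/d_i` where `d_i` is its Mendelian
#' sampling variance (`0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, `1` with none).
#'
#' @param ped An ordered pedigree.
#' @return A sparse symmetric `Matrix::dsCMatrix` equal to `solve(A)`.
#' @export
inverse_relationship_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  Fcoef <- inbreeding(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dmv <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
           else if (s > 0L) 0.75 - 0.25 * Fcoef[s]
           else if (d > 0L) 0.75 - 0.25 * Fcoef[d]
           else 1
    if (dmv <= 0) stop("non-positive Mendelian sampling variance; singular A")
    a <- 1 / dmv
    add(i, i, a)
    for (p in c(s, d)) if (p > 0L) {
      add(i, p, -a / 2); add(p, i, -a / 2)
      add(p, p, a / 4)
    }
    if (s > 0L && d > 0L) {
      add(s, d, a / 4); add(d, s, a / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Write / read pedigree CSV (LINKAGE-style, `0` = unknown parent)
#'
#' @param ped Pedigree to write.
#' @param path File path.
#' @return `read_pedigree` returns an `oyster_pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "character"))
  ped <- data.frame(id = x$id,
                    sire = ifelse(x$sire == "0", NA_character_, x$sire),
                    dam = ifelse(x$dam == "0", NA_character_, x$dam),
                    generation = ifelse(x$sire == "0" & x$dam == "0",
                                        "founder", "offspring"),
                    site = NA_character_, sex = NA_character_,
                    stringsAsFactors = FALSE)
  class(ped) <- c("oyster_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Write / read cross-table CSV
#' @param crosses Cross table.
#' @param path File path.
#' @export
write_crosses <- function(crosses, path) {
  utils::write.csv(crosses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crosses
#' @export
read_crosses <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$fertilized <- as.logical(x$fertilized)
  x$family <- as.character(x$family)
  x$family[x$family == "" | x$family == "NA"] <- NA_character_
  x
}
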