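# NC II cross design and pedigree construction.

test_that("canonical 16-block design yields 128 crosses, 64 dams, 32 sires", {
  cr <- ncii_cross_table(16, 2, 1, 0, seed = 1)
  expect_equal(nrow(cr), 128)
  expect_equal(length(unique(cr$dam)), 64)
  expect_equal(length(unique(cr$sire)), 32)
  expect_true(all(table(cr$block) == 8))
  expect_false(any(duplicated(cr[, c("block", "dam", "sire")])))
})

test_that("a single block is a full factorial of its dams and sires", {
  cr <- ncii_cross_table(1, 2, 1, 0, seed = 2)
  expect_equal(nrow(cr), 8)
  expect_true(all(table(cr$dam) == 2))    # each dam meets both sires
  expect_true(all(table(cr$sire) == 4))   # each sire meets all four dams
})

test_that("dam reuse tuned to the realized experiment gives 19/21 distinct dams, 4 mates each", {
  cr <- ncii_cross_table(16, 2, 1, c(0.8125, 0.6875), seed = 3)
  dd <- unique(cr[, c("dam", "dam_site")])
  expect_equal(sum(dd$dam_site == "LOW"), 19)
  expect_equal(sum(dd$dam_site == "MEDIUM"), 21)
  blocks_per_dam <- rowSums(table(cr$dam, cr$block) > 0)
  expect_true(all(blocks_per_dam <= 2))
  reused <- names(blocks_per_dam)[blocks_per_dam == 2]
  mates <- vapply(reused, function(d) length(unique(cr$sire[cr$dam == d])), 1L)
  expect_true(all(mates == 4))
  # sires never reused
  expect_true(all(rowSums(table(cr$sire, cr$block) > 0) == 1))
})

test_that("reuse with a single block is rejected", {
  expect_error(ncii_cross_table(1, 2, 1, 0.5, seed = 1), "two blocks")
})

test_that("pedigree materializes founders first, then family offspring", {
  cr <- ncii_cross_table(1, 2, 1, 0, seed = 1)[1, ]
  cr$fertilized <- TRUE; cr$family <- "FAM001"
  ped <- pedigree_from_crosses(cr, 3)
  expect_s3_class(ped, "oyster_pedigree")
  expect_equal(sum(ped$generation == "founder"), 2)
  expect_equal(sum(ped$generation == "offspring"), 3)
  expect_true(all(which(ped$generation == "founder") <
                  min(which(ped$generation == "offspring"))))
  off <- ped[ped$generation == "offspring", ]
  expect_true(all(off$sire == cr$sire & off$dam == cr$dam))
})

test_that("zero fertilized crosses give a founders-only pedigree", {
  cr <- ncii_cross_table(1, 2, 1, 0, seed = 1)
  cr$fertilized <- FALSE
  ped <- pedigree_from_crosses(cr, 5)
  expect_true(all(ped$generation == "founder"))
  expect_equal(nrow(ped), 6)  # 4 dams + 2 sires
})

test_that("default fertilization failure leaves about 40 families", {
  fams <- vapply(1:6, function(s) {
    cr <- simulate_fertilization(ncii_cross_table(16, seed = s),
                                 default_params(), seed = s)
    sum(cr$fertilized)
  }, 1L)
  expect_gt(mean(fams), 30)   # 128 x 0.32 = 41 expected
  expect_lt(mean(fams), 52)
})

test_that("pedigree validation rejects malformed structures", {
  ped <- data.frame(id = c("X", "X"), sire = NA_character_, dam = NA_character_)
  expect_error(validate_pedigree(ped), "unique")
  ped2 <- data.frame(id = c("P", "O"), sire = c(NA, "Z"), dam = c(NA, "P"))
  expect_error(validate_pedigree(ped2), "unknown")
  ped3 <- data.frame(id = c("O", "P", "Q"), sire = c("P", NA, NA),
                     dam = c("Q", NA, NA))  # offspring before parents
  expect_error(validate_pedigree(ped3), "ordered")
})

test_that("pedigree and cross-table CSV round-trips preserve structure", {
  cr <- ncii_cross_table(2, 2, 1, 0, seed = 5)
  cr <- simulate_fertilization(cr, default_params(), seed = 5)
  ped <- pedigree_from_crosses(cr, 2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_pedigree(ped, f1)
  back <- read_pedigree(f1)
  expect_equal(back$id, ped$id)
  expect_equal(back$sire, ped$sire)
  expect_equal(back$dam, ped$dam)
  expect_true(any(grepl(",0,0", readLines(f1), fixed = TRUE)))  # LINKAGE zeros
  write_crosses(cr, f2)
  cr2 <- read_crosses(f2)
  expect_equal(cr2$dam, cr$dam)
  expect_equal(cr2$fertilized, cr$fertilized)
  expect_equal(cr2$family, cr$family)
})
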