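test_that("structure-dialect round trip preserves tables exactly", {
  gt <- toy_table()
  path <- withr::local_tempfile(fileext = ".str")
  write_structure_table(gt, path)
  back <- read_structure_table(path, gt$panel)
  expect_identical(back$ids, gt$ids)
  expect_identical(back$labels, gt$labels)
  expect_identical(back$alleles, gt$alleles)
  # missing sentinel written as -9 in both columns
  line <- readLines(path)[2]
  expect_match(line, "-9 -9")
  # empty table round trip
  empty <- gt[integer(0)]
  write_structure_table(empty, path)
  back <- read_structure_table(path, gt$panel)
  expect_equal(n_individuals(back), 0L)
})

test_that("parser enforces row width and integer allele codes", {
  path <- withr::local_tempfile(fileext = ".str")
  writeLines("W01 RW 132 136 -9 -9", path)
  gt <- read_structure_table(path, c("A", "B"))
  expect_equal(unname(gt$alleles[1, 1:2]), c(132L, 136L))
  expect_true(all(is.na(gt$alleles[1, 3:4])))

  writeLines("W01 RW 132 136 140", path)
  expect_error(read_structure_table(path, c("A", "B")), "line 1")
  writeLines("W01 RW 132 136 -9 -9 101", path)
  expect_error(read_structure_table(path, c("A", "B")), "expected 6 fields")
  writeLines("W01 RW 132 13x -9 -9", path)
  expect_error(read_structure_table(path, c("A", "B")), "non-integer")
})

test_that("genotype_table validates its invariants", {
  expect_error(
    genotype_table("a", "RW", matrix(c(1L, NA), 1), "L1"),
    "missing together"
  )
  expect_error(
    genotype_table(c("a", "a"), c("RW", "RW"),
                   rbind(c(1L, 1L), c(1L, 2L)), "L1"),
    "unique"
  )
  expect_error(
    genotype_table("a", "RW", matrix(c(0L, 1L), 1), "L1"),
    "positive"
  )
})

test_that("subset_panel restricts and reorders loci", {
  gt <- toy_table()
  sub <- subset_panel(gt, "FH2088")
  expect_equal(sub$panel, "FH2088")
  expect_equal(unname(sub$alleles[1, ]), c(210L, 210L))
  expect_identical(sub$ids, gt$ids)
  # identity when keeping everything in order
  expect_identical(subset_panel(gt, gt$panel)$alleles, gt$alleles)
  # reversal reorders columns
  rev2 <- subset_panel(gt, rev(gt$panel))
  expect_equal(unname(rev2$alleles[1, ]), c(210L, 210L, 132L, 136L))
  expect_error(subset_panel(gt, c("FH2004", "TYPO")), "TYPO")
})

test_that("qc filter drops individuals at or above the missing threshold", {
  # 39-locus individual with 4 missing: 4/39 > 0.10, so removed at 0.10
  panel <- sprintf("L%02d", 1:39)
  a <- matrix(101L, 2, 78)
  a[2, 1:8] <- NA_integer_
  gt <- genotype_table(c("ok", "bad"), c("RW", "RW"), a, panel)
  kept <- qc_filter_genotypes(gt, 0.10)
  expect_equal(kept$ids, "ok")
  # complete genotypes survive any positive threshold
  expect_equal(n_individuals(qc_filter_genotypes(gt[1], 1e-9)), 1L)
  # threshold 0 removes even complete genotypes' peers with any missing;
  # complete ones need frac < 0, so none survive at exactly 0
  expect_equal(n_individuals(qc_filter_genotypes(gt, 0)), 0L)
  # surviving genotypes unmodified
  expect_identical(kept$alleles, gt$alleles[1, , drop = FALSE])
})

test_that("reference-candidate filter combines q and completeness", {
  gt <- toy_table()   # W02 has a missing locus
  q <- c(W01 = 0.995, W02 = 0.999, D01 = 0.985, H01 = 0.5)
  kept <- filter_reference_candidates(gt, q, min_q = 0.990)
  # W02 dropped for missing data despite q = 0.999; D01 dropped for low q
  expect_equal(kept$ids, "W01")
  expect_error(filter_reference_candidates(gt, q[-1], 0.990), "W01")
})

test_that("allele frequencies are plain counts over non-missing copies", {
  gt <- genotype_table(
    c("a", "b", "c"), c("G1", "G1", "G2"),
    rbind(c(132L, 132L, 101L, 101L),
          c(132L, 136L, NA, NA),
          c(140L, 140L, 101L, 101L)),
    c("L1", "L2")
  )
  af <- estimate_allele_frequencies(gt)
  expect_equal(af$freqs$L1["G1", ], c("132" = 0.75, "136" = 0.25, "140" = 0))
  expect_equal(af$freqs$L1["G2", ], c("132" = 0, "136" = 0, "140" = 1))
  # missing copies excluded from the denominator; L2 in G1 has 2 copies only
  expect_equal(unname(af$freqs$L2["G1", "101"]), 1)
  # rows always sum to one
  for (m in af$freqs) expect_equal(unname(rowSums(m)), rep(1, nrow(m)))
  # a group with no copies at a locus is an error
  gt2 <- genotype_table(
    c("a", "b"), c("G1", "G2"),
    rbind(c(132L, 132L), c(NA_integer_, NA_integer_)), "L1"
  )
  expect_error(estimate_allele_frequencies(gt2), "L1.*G2")
})
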