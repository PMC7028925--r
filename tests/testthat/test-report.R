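mk_classified <- function(q, labels) {
  df <- data.frame(individual_id = sprintf("id%02d", seq_along(q)),
                   label = labels, stringsAsFactors = FALSE)
  cbind(df, classify_individuals(q, threshold_pair(0.955, 0.995)))
}

test_that("evidence flags validate shape, values and sex consistency", {
  flags <- data.frame(individual_id = c("id01", "id02"),
                      dog_mtdna = c(0, 1), dog_y_haplotype = c(1, NA),
                      k_locus_deletion = c(0, 0), dog_like_phenotype = c(0, 1))
  expect_silent(validate_evidence_flags(flags))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(flags, path, row.names = FALSE)
  expect_equal(read_evidence_flags(path)$dog_mtdna, c(0, 1))

  bad <- flags
  bad$dog_mtdna[1] <- 2
  expect_error(validate_evidence_flags(bad), "0/1")
  sexed <- cbind(flags, sex = c("F", "F"))
  expect_error(validate_evidence_flags(sexed), "female")
  sexed$sex <- c("M", "F")
  expect_silent(validate_evidence_flags(sexed))
  expect_error(validate_evidence_flags(flags[, -2]), "missing flag columns")
})

test_that("evidence never reclassifies but annotates and cross-tabulates", {
  cl <- mk_classified(c(0.999, 0.998, 0.97, 0.4), c("RW", "RW", "BC3W", "F1"))
  flags <- data.frame(individual_id = c("id01", "id04"),
                      dog_mtdna = c(0, 1), dog_y_haplotype = c(1, 1),
                      k_locus_deletion = c(0, 1), dog_like_phenotype = c(0, 1))
  rep1 <- integrate_evidence(cl, flags)
  ind <- rep1$individuals
  # q-based category unchanged by the dog Y haplotype
  expect_equal(as.character(ind$management_category[1]), "operational pure")
  expect_true(ind$possible_older_introgression[1])
  expect_false(any(ind$possible_older_introgression[-1]))
  # category counts sum to the total
  expect_equal(sum(rep1$category_counts), nrow(ind))
  # male-only denominator: category 'operational pure' has 1 male, flagged
  expect_equal(unname(rep1$evidence_summary["operational pure",
                                            "pct_dog_y_of_males"]), 100)
  # unknown individual -> warning, not error
  flags2 <- rbind(flags, data.frame(individual_id = "ghost", dog_mtdna = 1,
                                    dog_y_haplotype = NA, k_locus_deletion = 0,
                                    dog_like_phenotype = 0))
  expect_warning(integrate_evidence(cl, flags2), "ghost")
  # no flags: report equals the classification counts
  rep0 <- integrate_evidence(cl)
  expect_equal(sum(rep0$category_counts), 4)
  expect_equal(unname(rep0$category_counts["operational pure"]), 2)
})

test_that("CI width statistics recover anti-correlation and group contrasts", {
  # toy: width exactly 1 - q
  q <- seq(0.1, 0.9, by = 0.1)
  res <- data.frame(individual_id = sprintf("i%d", 1:9),
                    label = rep(c("F1", "PW", "F1"), 3),
                    q_wild_mean = q,
                    q_wild_lo90 = q - (1 - q) / 2,
                    q_wild_hi90 = q + (1 - q) / 2)
  st <- ci_width_statistics(res)
  expect_equal(st$r, -1)
  # identical groups give t = 0
  res2 <- res
  res2$label <- rep(c("A", "B"), length.out = 9)
  res2$q_wild_lo90 <- res2$q_wild_mean - rep(c(0.1, 0.1), length.out = 9)
  res2$q_wild_hi90 <- res2$q_wild_mean + rep(c(0.2, 0.3, 0.4), 3) / 10
  widths <- res2$q_wild_hi90 - res2$q_wild_lo90
  same <- ci_width_statistics(res2, group_pairs = list(list("A", "A")))
  expect_equal(same$t_tests$t, 0)
  # zero-variance input errors
  res3 <- res
  res3$q_wild_lo90 <- res3$q_wild_mean - 0.1
  res3$q_wild_hi90 <- res3$q_wild_mean + 0.1
  expect_error(ci_width_statistics(res3), "zero variance")
})

test_that("the pipeline runs end to end and is byte-reproducible", {
  cfg <- list(n_loci = 12, n_alleles = 4, fst = 0.35, n_wild = 12, n_dom = 12,
              n_per_class = 3, n_burnin = 200, n_iter = 800, thin = 4,
              thresholds = c(0.955, 0.995), seed = 77)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, out1)
  r2 <- run_pipeline(cfg, out2)
  for (f in c("refs.str", "ladder.str", "q_table.csv", "grid.csv",
              "classes.csv", "confusion.csv")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$thresholds$t_recent, 0.955)
  expect_equal(manifest$config$seed, 77)
  expect_equal(nrow(r1$classified), 12 * 3)
  # fixed thresholds skip derivation
  expect_equal(r1$thresholds$t_pure, 0.995)
})
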