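test_that("complete separation drives memberships to opposite clusters", {
  # two individuals fixed for alternative alleles at 30 diagnostic loci
  a <- matrix(102L, 1, 60)
  b <- matrix(104L, 1, 60)
  gt <- genotype_table(c("w", "d"), c("RW", "RD"), rbind(a, b),
                       sprintf("L%02d", 1:30))
  fit <- align_clusters(admixture_fit(gt, mcmc_config(seed = 1)), "w")
  q <- colMeans(fit$q_samples)
  expect_gte(q[["w"]], 0.99)
  expect_lte(q[["d"]], 0.01)
})

test_that("posterior means match exact collapsed enumeration on 2-locus toys", {
  cfg <- mcmc_config(n_burnin = 4000, n_iter = 40000, thin = 5,
                     update_alpha = FALSE, alpha_init = 1, seed = 7)
  queries <- list(
    het_both = list(c(1, 2), c(1, 2)),
    het_hom = list(c(1, 2), c(1, 1)),
    hom_wild = list(c(1, 1), c(1, 1)),
    hom_dog_het = list(c(2, 2), c(1, 2))
  )
  for (nm in names(queries)) {
    qry <- queries[[nm]]
    exact <- oracle_admixture_toy(qry)
    fit <- align_clusters(admixture_fit(oracle_toy_table(qry), cfg),
                          paste0("W", 1:3))
    mcmc <- mean(fit$q_samples[, "Q"])
    expect_lt(abs(mcmc - exact), 0.02)
  }
})

test_that("results are invariant to seed up to Monte Carlo noise", {
  # alpha fixed, as in the enumeration oracle: on a 7-individual toy a
  # learned alpha wanders and would dominate the Monte Carlo noise
  qry <- list(c(1, 2), c(1, 1))
  tab <- oracle_toy_table(qry)
  cfg1 <- mcmc_config(n_burnin = 4000, n_iter = 40000, thin = 5, seed = 11,
                      update_alpha = FALSE)
  cfg2 <- mcmc_config(n_burnin = 4000, n_iter = 40000, thin = 5, seed = 22,
                      update_alpha = FALSE)
  f1 <- align_clusters(admixture_fit(tab, cfg1), paste0("W", 1:3))
  f2 <- align_clusters(admixture_fit(tab, cfg2), paste0("W", 1:3))
  expect_lt(max(abs(colMeans(f1$q_samples) - colMeans(f2$q_samples))), 0.02)
})

test_that("posterior samples and summaries respect simplex and CI invariants", {
  gt <- fx_refs()[c(1:10, 101:110)]
  fit <- align_clusters(
    admixture_fit(gt, mcmc_config(n_burnin = 1000, n_iter = 5000, seed = 2)),
    gt$ids[gt$labels == "RW"]
  )
  expect_true(all(fit$q_samples >= 0 & fit$q_samples <= 1))
  s <- summarize_q(fit)
  expect_equal(s$q_wild_mean + s$q_dom_mean, rep(1, nrow(s)))
  expect_true(all(s$q_wild_lo90 >= 0 & s$q_wild_hi90 <= 1))
  expect_true(all(s$q_wild_lo90 <= s$q_wild_mean + 1e-12))
  expect_true(all(s$q_wild_mean <= s$q_wild_hi90 + 1e-12))
  cf <- coef(fit)
  expect_equal(unname(rowSums(cf)), rep(1, nrow(cf)))
})

test_that("cluster anchoring flips degenerate orientations and errors on ties", {
  gt <- fx_refs()[c(1:5, 101:105)]
  fit <- admixture_fit(gt, mcmc_config(n_burnin = 500, n_iter = 2000, seed = 3))
  al <- align_clusters(fit, gt$ids[1:5])
  expect_gt(mean(al$q_samples[, 1:5]), 0.5)
  # aligning twice is a no-op
  expect_equal(align_clusters(al, gt$ids[1:5])$q_samples, al$q_samples)
  # anchoring to the domestic side flips the orientation
  flipped <- align_clusters(fit, gt$ids[6:10])
  expect_lt(mean(flipped$q_samples[, 1:5]), 0.5)
  # degenerate 50/50 loading errors
  degen <- fit
  degen$q_samples[] <- 0.5
  expect_error(align_clusters(degen, gt$ids[1:5]), "degenerate")
  expect_error(align_clusters(fit, "nobody"), "unknown")
})

test_that("one-by-one assignment is independent of query order", {
  refs <- fx_refs()[c(1:15, 101:115)]
  fr <- fx_freqs()
  f1 <- simulate_cross(freq_pool(fr, "wild"), freq_pool(fr, "domestic"),
                       "F1", 3, seed = 44)
  cfg <- mcmc_config(n_burnin = 500, n_iter = 2000, seed = 9)
  fwd <- assign_one_by_one(refs, f1, cfg, wild_labels = "RW")
  rev_ <- assign_one_by_one(refs, f1[3:1], cfg, wild_labels = "RW")
  m <- match(fwd$individual_id, rev_$individual_id)
  expect_equal(fwd$q_wild_mean, rev_$q_wild_mean[m])
  expect_equal(fwd$q_wild_lo90, rev_$q_wild_lo90[m])
  expect_error(assign_one_by_one(refs, refs[1], cfg, wild_labels = "RW"),
               "overlap")
})

test_that("group summaries average members and pool their draws", {
  df <- data.frame(individual_id = c("a", "b", "c"),
                   label = c("G1", "G1", "G2"),
                   q_wild_mean = c(0.9, 0.8, 0.5))
  gs <- summarize_groups(df)
  expect_equal(gs$Q_wild_mean[gs$label == "G1"], 0.85)
  # group of one equals the individual
  expect_equal(gs$Q_wild_mean[gs$label == "G2"], 0.5)
  expect_equal(gs$Q_wild_mean + gs$Q_dom_mean, rep(1, 2))
  expect_error(summarize_groups(df, labels = c("G1", NA, "G2")), "labelled")
})

test_that("run stability summarizes absolute differences across run pairs", {
  r1 <- c(a = 0.9, b = 0.5)
  expect_equal(unname(run_stability(r1, r1)), c(0, 0))
  expect_equal(unname(run_stability(r1, r1 + 0.01)), c(0.01, 0))
  # three runs: all pairs enter
  st <- run_stability(r1, r1 + 0.01, r1 - 0.01)
  expect_equal(unname(st[1]), mean(c(0.01, 0.02, 0.01)))
  expect_error(run_stability(r1, c(a = 0.9, z = 0.5)), "different individuals")
  expect_error(run_stability(r1), "two runs")
})
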