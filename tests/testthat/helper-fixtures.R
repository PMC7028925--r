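# Shared fixtures. Heavy MCMC products are memoized so several test files can
# reuse the same one-by-one assignment runs within a session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small handmade 2-locus table
toy_table <- function() {
  genotype_table(
    ids = c("W01", "W02", "D01", "H01"),
    labels = c("RW", "RW", "RD", "QUERY"),
    alleles = rbind(
      c(132L, 136L, 210L, 210L),
      c(132L, 132L, NA, NA),
      c(140L, 144L, 220L, 224L),
      c(132L, 140L, 210L, 220L)
    ),
    panel = c("FH2004", "FH2088")
  )
}

# two populations fixed for alternative alleles at every locus
fixed_difference_freqs <- function(n_loci = 1) {
  freqs <- lapply(seq_len(n_loci), function(l) {
    m <- rbind(wild = c(1, 0), domestic = c(0, 1))
    colnames(m) <- c("102", "104")
    m
  })
  names(freqs) <- sprintf("L%02d", seq_len(n_loci))
  allele_freqs(freqs, c("wild", "domestic"))
}

# --- study-condition fixture: two strongly differentiated reference
# populations at 39 loci (8 alleles each, Balding-Nichols F = 0.3),
# 100 wild + 95 domestic references, and a simulated hybrid ladder.

fx_freqs <- function() memo("freqs", {
  draw_parental_frequencies(39, 8, 0.30, seed = 101)
})

fx_refs <- function() memo("refs", {
  rbind_genotypes(
    sample_reference_population(fx_freqs(), "wild", 100, seed = 102,
                                label = "RW", prefix = "RW"),
    sample_reference_population(fx_freqs(), "domestic", 95, seed = 103,
                                label = "RD", prefix = "RD")
  )
})

fx_ladder <- function() memo("ladder", {
  build_class_ladder(fx_freqs(), 50, seed = 104)
})

# query subset used by the acceptance-level checks: all 50 F1, 20 PW,
# 20 BC1W, 14 of each remaining ladder class
fx_queries <- function() memo("queries", {
  lad <- fx_ladder()
  take <- function(cls, n) lad$ids[lad$labels == cls][seq_len(n)]
  ids <- c(take("PW", 20), take("F1", 50), take("F2", 14), take("BC1W", 20),
           unlist(lapply(paste0("BC", 2:8, "W"), take, n = 14)))
  lad[ids]
})

fx_config <- function() mcmc_config(n_burnin = 5000, n_iter = 20000,
                                    thin = 10, seed = 42)

# one-by-one assignment of the query subset (the expensive shared product)
fx_assignments <- function() memo("assignments", {
  assign_one_by_one(fx_refs(), fx_queries(), fx_config(), wild_labels = "RW")
})

# combined-panel run on the references alone, anchored
fx_reference_fit <- function() memo("reference_fit", {
  refs <- fx_refs()
  align_clusters(admixture_fit(refs, fx_config()),
                 refs$ids[refs$labels == "RW"])
})

# degraded copies (30% ADO + 30% missing) of the robustness subset
fx_robustness <- function() memo("robustness", {
  qs <- fx_queries()
  sub <- qs[qs$labels %in% c("PW", "F1", "BC1W")]
  sub <- sub[unlist(lapply(c("PW", "F1", "BC1W"),
                           function(cl) which(sub$labels == cl)[1:20]))]
  clean <- fx_assignments()
  clean <- clean[match(sub$ids, clean$individual_id), ]
  class(clean) <- c("assignment_set", "data.frame")
  degraded_tab <- inject_errors(sub, ado_rate = 0.3, missing_rate = 0.3,
                                seed = 105)
  # same per-query seeds: ids are unchanged, so derived seeds match
  degraded <- assign_one_by_one(fx_refs(), degraded_tab, fx_config(),
                                wild_labels = "RW", keep_draws = FALSE)
  list(clean = clean, degraded = degraded)
})

fx_thresholds <- function() memo("thresholds", {
  res <- fx_assignments()
  reft <- summarize_q(fx_reference_fit())
  q_all <- c(res$q_wild_mean, reft$q_wild_mean[reft$label == "RW"])
  lab_all <- c(res$label, reft$label[reft$label == "RW"])
  t_pure <- select_pure_threshold(q_all, lab_all,
                                  wild_parental_labels = c("RW", "PW"))
  grid <- performance_grid(res$q_wild_mean[res$label %in% ladder_classes()],
                           res$label[res$label %in% ladder_classes()])
  t_recent <- tryCatch(as.numeric(select_recent_threshold(grid)),
                       error = function(e) NA_real_)
  list(grid = grid, t_recent = t_recent, t_pure = t_pure)
})
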