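#' Read an evidence-flag table
#'
#' CSV with columns `individual_id`, `dog_mtdna` (0/1), `dog_y_haplotype`
#' (0/1, `NA` for females), `k_locus_deletion` (0/1), `dog_like_phenotype`
#' (0/1) and optionally `sex` (`"F"`/`"M"`). When `sex` is present, a female
#' with a non-missing Y-haplotype flag is a validation error.
#'
#' @param path CSV file path.
#' @return Validated data frame of evidence flags.
#' @export
read_evidence_flags <- function(path) {
  flags <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_evidence_flags(flags)
}

#' @rdname read_evidence_flags
#' @param flags A data frame of flags to validate.
#' @export
validate_evidence_flags <- function(flags) {
  need <- c("individual_id", "dog_mtdna", "dog_y_haplotype",
            "k_locus_deletion", "dog_like_phenotype")
  miss <- setdiff(need, names(flags))
  if (length(miss) > 0L) stop("missing flag columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(flags$individual_id)) stop("duplicated individual ids in flags")
  for (col in setdiff(need, "individual_id")) {
    v <- flags[[col]]
    if (!all(v %in% c(0, 1, NA))) stop("flag column ", col, " must be 0/1/NA")
  }
  if ("sex" %in% names(flags)) {
    bad <- flags$sex %in% c("F", "f", "female") & !is.na(flags$dog_y_haplotype)
    if (any(bad)) {
      stop("Y-haplotype flag set for female individual(s): ",
           paste(flags$individual_id[bad], collapse = ", "))
    }
  }
  flags
}

#' Integrate auxiliary marker evidence into a management report
#'
#' Joins uniparental (mtDNA, Y-linked STR haplotypes), K-locus and phenotype
#' evidence onto q-based classifications. Evidence flags never change the
#' q-based management category - they corroborate it (e.g. a dog Y haplotype
#' in an operationally pure individual flags possible older introgression).
#' Y-haplotype percentages use males only as denominator (individuals with a
#' non-missing Y flag).
#'
#' @param classified Output of [classify_individuals()] with `individual_id`.
#' @param flags Optional evidence-flag data frame (see
#'   [read_evidence_flags()]); flags for unknown individuals raise a warning.
#' @return A `management_report`: list with the per-individual table
#'   (`individuals`), per-category counts (`category_counts`) and the
#'   evidence cross-tabulation (`evidence_summary`, percentages per
#'   category).
#' @export
integrate_evidence <- function(classified, flags = NULL) {
  stopifnot(all(c("individual_id", "management_category") %in% names(classified)))
  indiv <- classified
  flag_cols <- c("dog_mtdna", "dog_y_haplotype", "k_locus_deletion",
                 "dog_like_phenotype")
  if (!is.null(flags)) {
    flags <- validate_evidence_flags(flags)
    unknown <- setdiff(flags$individual_id, classified$individual_id)
    if (length(unknown) > 0L) {
      warning("evidence flags for unknown individual(s): ",
              paste(unknown, collapse = ", "))
    }
    m <- match(indiv$individual_id, flags$individual_id)
    for (col in flag_cols) indiv[[col]] <- flags[[col]][m]
    indiv$possible_older_introgression <-
      indiv$management_category == "operational pure" &
      (indiv$dog_mtdna %in% 1 | indiv$dog_y_haplotype %in% 1)
  } else {
    for (col in flag_cols) indiv[[col]] <- NA_real_
    indiv$possible_older_introgression <- FALSE
  }
  cats <- management_category_levels()
  counts <- table(factor(indiv$management_category, levels = cats))
  ev <- t(vapply(cats, function(cc) {
    sel <- indiv$management_category == cc
    n <- sum(sel)
    n_males <- sum(sel & !is.na(indiv$dog_y_haplotype))
    c(n = n,
      pct_of_total = 100 * n / nrow(indiv),
      pct_dog_mtdna = if (n > 0) 100 * mean(indiv$dog_mtdna[sel] %in% 1) else NA,
      pct_dog_y_of_males = if (n_males > 0)
        100 * sum(indiv$dog_y_haplotype[sel] %in% 1) / n_males else NA,
      pct_k_locus = if (n > 0) 100 * mean(indiv$k_locus_deletion[sel] %in% 1) else NA)
  }, numeric(5)))
  structure(list(individuals = indiv,
                 category_counts = counts,
                 evidence_summary = ev),
            class = "management_report")
}

#' @export
print.management_report <- function(x, ...) {
  cat("management_report:", nrow(x$individuals), "individuals\n")
  print(x$category_counts)
  print(round(x$evidence_summary, 1))
  invisible(x)
}

#' Credibility-interval width diagnostics
#'
#' Admixed individuals carry wider posterior credibility intervals than
#' parentals because their per-locus ancestry is genuinely mixed. This
#' returns the Pearson correlation between 90% CI width and wild membership
#' (expected strongly negative) and Welch t-tests comparing mean CI width
#' between named groups.
#'
#' @param results An `assignment_set` (or data frame with `q_wild_mean`,
#'   `q_wild_lo90`, `q_wild_hi90`, `label`).
#' @param group_pairs List of 2-element character vectors; for each pair
#'   `c(a, b)` a Welch t-test of CI width in labels-in-a vs labels-in-b is
#'   run. Elements may be vectors of labels.
#' @return List with `r`, `r_p_value` and a data frame `t_tests`
#'   (`group_a`, `group_b`, `t`, `p_value`, `mean_width_a`, `mean_width_b`).
#' @export
ci_width_statistics <- function(results, group_pairs = NULL) {
  if (nrow(results) < 3L) stop("need at least 3 individuals")
  width <- results$q_wild_hi90 - results$q_wild_lo90
  if (stats::sd(width) < 1e-12 || stats::sd(results$q_wild_mean) < 1e-12) {
    stop("zero variance in CI widths or q values; correlation undefined")
  }
  ct <- stats::cor.test(width, results$q_wild_mean)
  tt <- NULL
  if (!is.null(group_pairs)) {
    tt <- do.call(rbind, lapply(group_pairs, function(pair) {
      wa <- width[results$label %in% pair[[1L]]]
      wb <- width[results$label %in% pair[[2L]]]
      ht <- stats::t.test(wa, wb)
      data.frame(group_a = paste(pair[[1L]], collapse = "+"),
                 group_b = paste(pair[[2L]], collapse = "+"),
                 t = unname(ht$statistic), p_value = ht$p.value,
                 mean_width_a = mean(wa), mean_width_b = mean(wb),
                 stringsAsFactors = FALSE)
    }))
  }
  list(r = unname(ct$estimate), r_p_value = ct$p.value, t_tests = tt)
}

#' Run the full simulation-to-classification pipeline
#'
#' Orchestrates: synthetic reference generation, hybrid-ladder simulation,
#' optional error injection, one-by-one admixture assignment, performance
#' analysis with threshold selection (or fixed thresholds), classification,
#' error accounting and report writing. All intermediate tables are written
#' as CSV under `out_dir`, together with a JSON run manifest recording seeds
#' and the configuration. Deterministic given `config$seed`.
#'
#' @param config List with entries (all optional, defaults shown):
#'   `n_loci` (39), `n_alleles` (8), `fst` (0.30), `n_wild` (100),
#'   `n_dom` (95), `n_per_class` (100), `ado_rate` (0), `missing_rate` (0),
#'   `n_burnin` (5000), `n_iter` (20000), `thin` (10),
#'   `thresholds` (`NULL` to derive from the performance analysis, or
#'   `c(t_recent, t_pure)` to fix), `seed` (1).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the assignment set, grid, thresholds,
#'   classification, error rates and file paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("hybridgate_run_")) {
  defaults <- list(n_loci = 39, n_alleles = 8, fst = 0.30, n_wild = 100,
                   n_dom = 95, n_per_class = 100, ado_rate = 0,
                   missing_rate = 0, n_burnin = 5000, n_iter = 20000,
                   thin = 10, thresholds = NULL, seed = 1)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf(name, "start")
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf(name, "done")
    res
  }
  seeds <- with_seed(cfg$seed, sample.int(2^31 - 1, 6))

  freqs <- stage("simulate-refs", draw_parental_frequencies(
    cfg$n_loci, cfg$n_alleles, cfg$fst, seed = seeds[1L]))
  refs <- stage("simulate-refs", rbind_genotypes(
    sample_reference_population(freqs, "wild", cfg$n_wild, seed = seeds[2L],
                                label = "RW", prefix = "RW"),
    sample_reference_population(freqs, "domestic", cfg$n_dom, seed = seeds[3L],
                                label = "RD", prefix = "RD")))
  write_structure_table(refs, file.path(out_dir, "refs.str"))

  ladder <- stage("simulate-hybrids",
                  build_class_ladder(freqs, cfg$n_per_class, seed = seeds[4L]))
  if (cfg$ado_rate > 0 || cfg$missing_rate > 0) {
    ladder <- stage("inject-errors",
                    inject_errors(ladder, cfg$ado_rate, cfg$missing_rate,
                                  seed = seeds[5L]))
  }
  write_structure_table(ladder, file.path(out_dir, "ladder.str"))

  mc <- mcmc_config(n_burnin = cfg$n_burnin, n_iter = cfg$n_iter,
                    thin = cfg$thin, seed = seeds[6L])
  res <- stage("assign", assign_one_by_one(refs, ladder, mc,
                                           wild_labels = "RW"))
  utils::write.csv(as.data.frame(res), file.path(out_dir, "q_table.csv"),
                   row.names = FALSE)

  wild_side <- res$label %in% ladder_classes()
  grid <- stage("performance", performance_grid(res$q_wild_mean[wild_side],
                                                res$label[wild_side]))
  utils::write.csv(grid, file.path(out_dir, "grid.csv"), row.names = FALSE)

  thr <- stage("thresholds", {
    if (!is.null(cfg$thresholds)) {
      threshold_pair(cfg$thresholds[1L], cfg$thresholds[2L])
    } else {
      threshold_pair(select_recent_threshold(grid),
                     select_pure_threshold(res$q_wild_mean, res$label))
    }
  })

  classified <- stage("classify", classify_individuals(res, thr))
  utils::write.csv(classified, file.path(out_dir, "classes.csv"),
                   row.names = FALSE)
  err <- stage("report", error_rates(classified))
  report <- stage("report", integrate_evidence(classified))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridgate")),
    config = cfg[setdiff(names(cfg), "thresholds")],
    thresholds = list(t_recent = thr$t_recent, t_pure = thr$t_pure),
    stage_seeds = seeds,
    type_I = err$type_I, type_II = err$type_II
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame.matrix(err$confusion),
                   file.path(out_dir, "confusion.csv"))

  invisible(list(freqs = freqs, references = refs, ladder = ladder,
                 assignments = res, grid = grid, thresholds = thr,
                 classified = classified, error_rates = err,
                 report = report, out_dir = out_dir))
}
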