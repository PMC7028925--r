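#' Inject allelic dropout into a genotype table
#'
#' Allelic dropout (ADO) turns a heterozygote into a false homozygote when
#' one allele fails to amplify. Independently for each heterozygous
#' locus-call, with probability `rate` one of the two alleles (chosen
#' uniformly) is overwritten by the other. Homozygous and missing calls are
#' untouched; no new alleles are ever created.
#'
#' @param table A `genotype_table`.
#' @param rate Per-heterozygous-call dropout probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `genotype_table` with dropout applied.
#' @export
inject_ado <- function(table, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(table)
  a <- table$alleles
  L <- n_loci(table)
  with_seed(seed, {
    for (l in seq_len(L)) {
      c1 <- 2L * l - 1L
      c2 <- 2L * l
      het <- which(!is.na(a[, c1]) & a[, c1] != a[, c2])
      if (length(het) == 0L) next
      hit <- het[stats::runif(length(het)) < rate]
      if (length(hit) == 0L) next
      keep_first <- stats::runif(length(hit)) < 0.5
      a[hit[keep_first], c2] <- a[hit[keep_first], c1]
      a[hit[!keep_first], c1] <- a[hit[!keep_first], c2]
    }
    genotype_table(table$ids, table$labels, a, table$panel)
  })
}

#' Inject missing data into a genotype table
#'
#' Independently per individual x locus, with probability `rate` the call is
#' set to missing (both allele copies).
#'
#' @param table A `genotype_table`.
#' @param rate Per-locus-call missingness probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `genotype_table` with missing calls injected.
#' @export
inject_missing <- function(table, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(table)
  a <- table$alleles
  n <- n_individuals(table)
  L <- n_loci(table)
  with_seed(seed, {
    drop <- matrix(stats::runif(n * L) < rate, n, L)
    for (l in seq_len(L)) {
      a[drop[, l], c(2L * l - 1L, 2L * l)] <- NA_integer_
    }
    genotype_table(table$ids, table$labels, a, table$panel)
  })
}

#' Apply allelic dropout then missingness
#'
#' Fixed composition order: dropout first, then missingness, so a
#' dropped-out call can still go missing — the convention used when both
#' error processes are simulated at the same nominal rate.
#'
#' @param table A `genotype_table`.
#' @param ado_rate,missing_rate Rates in `[0, 1]`.
#' @param seed Integer seed (sub-seeds for the two stages are derived from it).
#' @return A degraded `genotype_table`.
#' @export
inject_errors <- function(table, ado_rate, missing_rate, seed = 1) {
  seeds <- with_seed(seed, sample.int(2^31 - 1, 2))
  inject_missing(inject_ado(table, ado_rate, seed = seeds[1L]),
                 missing_rate, seed = seeds[2L])
}

#' Mean absolute discrepancy between two sets of membership coefficients
#'
#' Robustness statistic for genotyping error: the mean absolute difference in
#' wild-cluster membership between assignments of clean and degraded copies
#' of the same individuals (on the 0-1 q scale, so "2%" means 0.02).
#'
#' @param q_clean,q_degraded Named numeric vectors of wild-cluster membership
#'   (names are individual ids), or `assignment_set` objects.
#' @return Mean absolute difference of q across individuals.
#' @export
assignment_discrepancy <- function(q_clean, q_degraded) {
  q_clean <- as_q_vector(q_clean)
  q_degraded <- as_q_vector(q_degraded)
  if (!setequal(names(q_clean), names(q_degraded)) ||
      length(q_clean) != length(q_degraded)) {
    stop("the two assignments cover different individuals")
  }
  mean(abs(q_clean - q_degraded[names(q_clean)]))
}

as_q_vector <- function(x) {
  if (inherits(x, "assignment_set")) {
    stats::setNames(x$q_wild_mean, x$individual_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a named numeric vector or an assignment_set")
  }
}
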