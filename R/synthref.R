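#' Draw differentiated parental allele frequencies (Balding-Nichols model)
#'
#' Generates allele frequencies for two (or more) parental populations with a
#' controlled level of differentiation. Ancestral frequencies at each locus
#' are drawn from a symmetric Dirichlet; each population's frequencies are
#' then drawn from `Dirichlet(ancestral * (1 - F) / F)`, the multiallelic
#' Balding-Nichols construction, so that `F` is the expected fixation index
#' between each population and the ancestral pool. This stands in for a pair
#' of strongly differentiated empirical reference populations (e.g. wolves
#' and dogs typed at 39 microsatellites).
#'
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus (scalar or per-locus vector), `>= 2`.
#' @param fst Target differentiation, in `(0, 0.95)`.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param populations Population names (default `c("wild", "domestic")`).
#' @param ancestral_concentration Symmetric Dirichlet concentration for the
#'   ancestral frequencies (default 1, uniform over the simplex).
#' @param locus_names Optional locus names (default `L01`, `L02`, ...).
#' @return An `allele_freqs` object with one row per population at each
#'   locus. Allele codes mimic microsatellite sizes (even integers from 100).
#' @export
draw_parental_frequencies <- function(n_loci = 39, n_alleles = 8, fst = 0.30,
                                      seed = 1,
                                      populations = c("wild", "domestic"),
                                      ancestral_concentration = 1,
                                      locus_names = NULL) {
  if (fst <= 0 || fst >= 0.95) stop("fst must be in (0, 0.95)")
  n_alleles <- rep_len(as.integer(n_alleles), n_loci)
  if (any(n_alleles < 2L)) stop("alleles_per_locus must be >= 2")
  if (is.null(locus_names)) {
    locus_names <- sprintf("L%02d", seq_len(n_loci))
  }
  scale <- (1 - fst) / fst
  with_seed(seed, {
    freqs <- vector("list", n_loci)
    names(freqs) <- locus_names
    for (l in seq_len(n_loci)) {
      J <- n_alleles[l]
      anc <- stats::rgamma(J, shape = ancestral_concentration)
      anc <- anc / sum(anc)
      codes <- as.character(100L + 2L * seq_len(J))
      m <- matrix(0, length(populations), J,
                  dimnames = list(populations, codes))
      for (k in seq_along(populations)) {
        f <- stats::rgamma(J, shape = anc * scale)
        if (sum(f) == 0) f <- anc   # numerically degenerate draw
        m[k, ] <- f / sum(f)
      }
      freqs[[l]] <- m
    }
    allele_freqs(freqs, populations)
  })
}

#' Sample a reference population under Hardy-Weinberg proportions
#'
#' Each individual's genotype at each locus consists of two independent draws
#' from the population's allele-frequency vector; no missing data.
#'
#' @param freqs An `allele_freqs` object.
#' @param population Name of the population (row) to sample from.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param label Class label for the sampled individuals (defaults to
#'   `population`).
#' @param prefix Id prefix (defaults to `label`).
#' @return A `genotype_table` of `n` complete genotypes.
#' @export
sample_reference_population <- function(freqs, population, n, seed = 1,
                                        label = population, prefix = label) {
  if (!population %in% freqs$groups) {
    stop("unknown population label: ", population)
  }
  stopifnot(n >= 1)
  L <- length(freqs$freqs)
  with_seed(seed, {
    alleles <- matrix(NA_integer_, n, 2L * L)
    for (l in seq_len(L)) {
      f <- freqs$freqs[[l]][population, ]
      codes <- as.integer(names(f))
      draws <- sample(codes, 2L * n, replace = TRUE, prob = f)
      alleles[, 2L * l - 1L] <- draws[seq_len(n)]
      alleles[, 2L * l] <- draws[n + seq_len(n)]
    }
    genotype_table(sprintf("%s_%03d", prefix, seq_len(n)),
                   rep(label, n), alleles, freqs$panel)
  })
}

#' Multi-locus Weir-Cockerham differentiation between two samples
#'
#' Computes the Weir & Cockerham (1984) theta estimator of FST over all
#' shared polymorphic loci, the standard sample-size-corrected moment
#' estimator for codominant data, used here to validate the realized
#' divergence of synthetic reference populations.
#'
#' @param table_a,table_b `genotype_table`s sharing the same panel.
#' @return The multi-locus theta estimate (ratio of summed variance
#'   components).
#' @export
realized_fst <- function(table_a, table_b) {
  if (!identical(table_a$panel, table_b$panel)) stop("tables do not share a panel")
  r <- 2
  num <- 0
  den <- 0
  any_poly <- FALSE
  for (l in seq_along(table_a$panel)) {
    cols <- c(2L * l - 1L, 2L * l)
    ga <- table_a$alleles[, cols, drop = FALSE]
    gb <- table_b$alleles[, cols, drop = FALSE]
    ga <- ga[stats::complete.cases(ga), , drop = FALSE]
    gb <- gb[stats::complete.cases(gb), , drop = FALSE]
    n_i <- c(nrow(ga), nrow(gb))
    if (any(n_i < 2L)) next
    support <- sort(unique(c(as.vector(ga), as.vector(gb))))
    if (length(support) < 2L) next
    any_poly <- TRUE
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in support) {
      p_i <- c(mean(ga == al), mean(gb == al))
      h_i <- c(mean((ga[, 1L] == al) != (ga[, 2L] == al)),
               mean((gb[, 1L] == al) != (gb[, 2L] == al)))
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (!any_poly) stop("no shared polymorphic loci")
  num / den
}
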