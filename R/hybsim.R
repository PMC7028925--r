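#' Admixture class ladder
#'
#' The twelve simulated classes: wild (PW) and domestic (PD) parentals, first
#' (F1) and second (F2) generation hybrids, and eight successive backcross
#' generations toward the wild population (BC1W-BC8W).
#'
#' @return Character vector of the class names in ladder order.
#' @export
cross_classes <- function() {
  c("PW", "PD", "F1", "F2", paste0("BC", 1:8, "W"))
}

#' Expected domestic ancestry of a hybrid class
#'
#' The neutral pedigree expectation of the domestic ancestry fraction:
#' 0 for PW, 1 for PD, 1/2 for F1 and F2, and `0.5^(n+1)` for the n-th
#' backcross toward the wild population, so BC8W retains less than 0.2%
#' domestic ancestry in expectation.
#'
#' @param class Character vector of class names (see [cross_classes()]).
#' @return Numeric vector of expected domestic ancestry proportions.
#' @examples
#' expected_domestic_ancestry(c("F1", "BC1W", "BC8W"))
#' @export
expected_domestic_ancestry <- function(class) {
  vapply(as.character(class), function(cl) {
    if (cl == "PW") return(0)
    if (cl == "PD") return(1)
    if (cl %in% c("F1", "F2")) return(0.5)
    m <- regmatches(cl, regexec("^BC([1-8])W$", cl))[[1L]]
    if (length(m) == 2L) return(0.5^(as.integer(m[2L]) + 1L))
    stop("unknown class: ", cl)
  }, numeric(1))
}

# A gamete pool: either a frequency pool (population row of an allele_freqs)
# or a genotype pool (simulated individuals).
#' Frequency-pool gamete source
#'
#' Wraps one population of an `allele_freqs` object as a gamete source for
#' [simulate_cross()]: each gamete is an independent draw per locus from the
#' population's allele-frequency vectors.
#'
#' @param freqs An `allele_freqs` object.
#' @param population Population (row) name.
#' @return A `freq_pool` object.
#' @export
freq_pool <- function(freqs, population) {
  if (!population %in% freqs$groups) stop("unknown population label: ", population)
  structure(list(freqs = freqs, population = population),
            class = "freq_pool")
}

# draw n gametes (n x L allele matrix) from a pool
draw_gametes <- function(pool, n) {
  if (inherits(pool, "freq_pool")) {
    L <- length(pool$freqs$freqs)
    g <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      f <- pool$freqs$freqs[[l]][pool$population, ]
      g[, l] <- sample(as.integer(names(f)), n, replace = TRUE, prob = f)
    }
    g
  } else if (inherits(pool, "genotype_table")) {
    if (n_individuals(pool) == 0L) stop("empty genotype pool")
    L <- n_loci(pool)
    parent <- sample.int(n_individuals(pool), n, replace = TRUE)
    g <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      copy <- sample(c(2L * l - 1L, 2L * l), n, replace = TRUE)
      g[, l] <- pool$alleles[cbind(parent, copy)]
    }
    if (anyNA(g)) stop("gamete drawn from a missing locus; pools must be complete")
    g
  } else {
    stop("gamete pool must be a freq_pool or genotype_table")
  }
}

pool_panel <- function(pool) {
  if (inherits(pool, "freq_pool")) pool$freqs$panel else pool$panel
}

#' Simulate pure parental genotypes
#'
#' Hardy-Weinberg draws from the wild or domestic parental frequency pool,
#' labelled PW or PD.
#'
#' @param freqs An `allele_freqs` object with populations `wild` and
#'   `domestic`.
#' @param class `"PW"` (wild parentals) or `"PD"` (domestic parentals).
#' @param n Number of genotypes to simulate.
#' @param seed Integer seed.
#' @return A `genotype_table` with `n` rows labelled `class`.
#' @export
simulate_parentals <- function(freqs, class = c("PW", "PD"), n = 100, seed = 1) {
  class <- match.arg(class)
  pop <- if (class == "PW") "wild" else "domestic"
  if (!pop %in% freqs$groups) stop("frequency pool lacks population: ", pop)
  sample_reference_population(freqs, pop, n, seed = seed, label = class,
                              prefix = class)
}

#' Simulate a hybrid cross by Mendelian gamete sampling
#'
#' Each offspring receives one gamete from each parental pool. A gamete from
#' a frequency pool is an independent per-locus draw from the population's
#' allele frequencies; a gamete from a genotype pool picks a random parent
#' individual and transmits one of its two alleles per locus (Mendelian
#' segregation with unlinked loci), preserving the within-individual ancestry
#' correlation of simulated hybrids.
#'
#' @param parent_pool_a,parent_pool_b Gamete sources: `genotype_table` or
#'   [freq_pool()] objects sharing the same panel.
#' @param class_name Label for the offspring (e.g. `"F1"`, `"BC1W"`).
#' @param n Number of offspring.
#' @param seed Integer seed.
#' @return A `genotype_table` of `n` offspring labelled `class_name`.
#' @export
simulate_cross <- function(parent_pool_a, parent_pool_b, class_name, n = 100,
                           seed = 1) {
  panel <- pool_panel(parent_pool_a)
  if (!identical(panel, pool_panel(parent_pool_b))) {
    stop("parental pools do not share a panel")
  }
  stopifnot(n >= 1)
  with_seed(seed, {
    ga <- draw_gametes(parent_pool_a, n)
    gb <- draw_gametes(parent_pool_b, n)
    alleles <- matrix(NA_integer_, n, 2L * length(panel))
    alleles[, seq(1L, 2L * length(panel), by = 2L)] <- ga
    alleles[, seq(2L, 2L * length(panel), by = 2L)] <- gb
    genotype_table(sprintf("%s_%03d", class_name, seq_len(n)),
                   rep(class_name, n), alleles, panel)
  })
}

#' Build the full ladder of simulated admixture classes
#'
#' Simulates `n_per_class` genotypes for each of the twelve classes:
#' PW and PD (Hardy-Weinberg draws from the parental frequency pools),
#' F1 = wild x domestic gametes, F2 = F1 x F1, BC1W = F1 x wild pool, and
#' BCkW = BC(k-1)W x wild pool for k = 2..8. Backcross wild gametes are drawn
#' from the wild frequency pool; hybrid-side gametes are drawn from the
#' simulated individuals of the previous generation.
#'
#' @param freqs An `allele_freqs` object with populations `wild` and
#'   `domestic`.
#' @param n_per_class Genotypes per class (default 100, i.e. 1200 in total).
#' @param seed Integer seed.
#' @return A `genotype_table` with `12 * n_per_class` rows labelled by class.
#' @export
build_class_ladder <- function(freqs, n_per_class = 100, seed = 1) {
  stopifnot(n_per_class >= 2)
  wild <- freq_pool(freqs, "wild")
  dom <- freq_pool(freqs, "domestic")
  seeds <- with_seed(seed, sample.int(2^31 - 1, 12))
  pw <- simulate_parentals(freqs, "PW", n_per_class, seed = seeds[1L])
  pd <- simulate_parentals(freqs, "PD", n_per_class, seed = seeds[2L])
  f1 <- simulate_cross(wild, dom, "F1", n_per_class, seed = seeds[3L])
  f2 <- simulate_cross(f1, f1, "F2", n_per_class, seed = seeds[4L])
  out <- list(pw, pd, f1, f2)
  prev <- f1
  for (k in 1:8) {
    bck <- simulate_cross(prev, wild, paste0("BC", k, "W"), n_per_class,
                          seed = seeds[4L + k])
    out[[length(out) + 1L]] <- bck
    prev <- bck
  }
  do.call(rbind_genotypes, out)
}
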