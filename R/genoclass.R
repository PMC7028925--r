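#' Genotype-frequency class expectations
#'
#' The five hybrid classes distinguishable from single-generation genotype
#' frequencies, each defined by the Mendelian probability vector
#' `(g0, g1, g2)` that a locus carries 0, 1 or 2 domestic-origin allele
#' copies: pure wild (PW), pure domestic (PD), first- and second-generation
#' hybrids (F1, F2) and first backcrosses to the wild population (BC1W).
#'
#' @return A 5 x 3 matrix with rows PW, PD, F1, F2, BC1W and columns
#'   `g0`, `g1`, `g2`.
#' @export
class_g_vectors <- function() {
  m <- rbind(
    PW   = c(1, 0, 0),
    PD   = c(0, 0, 1),
    F1   = c(0, 1, 0),
    F2   = c(0.25, 0.5, 0.25),
    BC1W = c(0.5, 0.5, 0)
  )
  colnames(m) <- c("g0", "g1", "g2")
  m
}

#' Fit the five-class genotype-frequency model
#'
#' Gibbs sampler over latent per-individual hybrid classes, per-locus origin
#' states and the two parental allele-frequency sets, mixing references and
#' test individuals in one run without any individual or allele-frequency
#' prior information. Priors follow the two standard choices: "jeffreys"
#' (Dirichlet concentration 1/number-of-alleles per locus for frequencies and
#' 1/5 for class mixing proportions) or "uniform" (concentration 1 for both).
#'
#' Class labels are symmetric in the model up to swapping the two parental
#' pools; orientation is anchored by initialising individuals labelled as
#' wild/domestic references at the PW/PD classes (initialisation only, not a
#' prior).
#'
#' @param table A `genotype_table` containing reference and test individuals.
#' @param prior `"jeffreys"` or `"uniform"`.
#' @param config An [mcmc_config()]; defaults to a desk-scale chain of
#'   2e3 burn-in + 1e4 sweeps (use 1e4/1e5 for full-length runs).
#' @param wild_labels,dom_labels Labels used to anchor the orientation at
#'   initialisation.
#' @return An object of class `genoclass_fit` with the posterior class
#'   probability matrix (`posterior`, individuals x 5), maximum a posteriori
#'   class (`map_class`), ids and labels.
#' @export
genoclass_fit <- function(table, prior = c("jeffreys", "uniform"),
                          config = mcmc_config(n_burnin = 2000, n_iter = 10000,
                                               thin = 5),
                          wild_labels = c("RW", "wild", "PW"),
                          dom_labels = c("RD", "domestic", "PD")) {
  prior <- match.arg(prior)
  stopifnot(inherits(table, "genotype_table"))
  if (n_individuals(table) < 2L) stop("at least 2 individuals are required")
  rc <- recode_alleles(table)
  classes <- rownames(class_g_vectors())
  z_init <- integer(n_individuals(table))            # 0-based: PW
  z_init[table$labels %in% dom_labels] <- 1L         # PD
  z_init[!(table$labels %in% c(wild_labels, dom_labels))] <- 3L  # F2
  freq_prior <- if (prior == "jeffreys") 1 / rc$n_alleles
                else rep(1, length(rc$n_alleles))
  pi_prior <- if (prior == "jeffreys") 1 / length(classes) else 1
  res <- .genoclass_gibbs_cpp(rc$geno, rc$n_alleles, z_init,
                              config$n_burnin, config$n_iter, config$thin,
                              pi_prior, as.numeric(freq_prior),
                              as.double(config$seed))
  post <- res$post
  dimnames(post) <- list(table$ids, classes)
  structure(list(posterior = post,
                 map_class = classes[max.col(post, ties.method = "first")],
                 ids = table$ids, labels = table$labels,
                 prior = prior, config = config,
                 pi_samples = res$pi),
            class = "genoclass_fit")
}

#' @export
print.genoclass_fit <- function(x, ...) {
  cat(sprintf("genoclass_fit: %d individuals, 5 classes, %s priors\n",
              length(x$ids), x$prior))
  print(table(MAP = x$map_class))
  invisible(x)
}

#' @export
coef.genoclass_fit <- function(object, ...) object$posterior

#' @export
summary.genoclass_fit <- function(object, ...) {
  as.data.frame.genoclass_fit(object)
}

#' @export
as.data.frame.genoclass_fit <- function(x, ...) {
  cbind(data.frame(individual_id = x$ids, label = x$labels,
                   map_class = x$map_class, stringsAsFactors = FALSE),
        as.data.frame(x$posterior, row.names = FALSE))
}

#' Chi-square agreement test between two classification count vectors
#'
#' Pearson chi-square test comparing per-category counts produced by two
#' assignment methods (e.g. threshold classification of admixture
#' coefficients vs genotype-class posteriors). Categories with zero total
#' count are collapsed out before testing.
#'
#' @param counts_a,counts_b Named or aligned numeric vectors of per-category
#'   counts.
#' @return List with `statistic` (X-squared), `df` and `p.value`.
#' @export
compare_method_agreement <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) stop("count vectors must align")
  keep <- (counts_a + counts_b) > 0
  m <- rbind(counts_a[keep], counts_b[keep])
  if (identical(m[1L, ], m[2L, ])) {
    return(list(statistic = 0, df = sum(keep) - 1L, p.value = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
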