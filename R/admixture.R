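#' MCMC configuration for the Bayesian samplers
#'
#' Chain controls for [admixture_fit()] and [genoclass_fit()]. The defaults
#' are a desk-scale chain (5e3 burn-in + 2e4 sweeps) that reproduces
#' full-length runs to within typical Monte Carlo noise on strongly
#' differentiated reference panels; set `n_burnin = 5e4, n_iter = 5e5` for
#' full-length admixture runs.
#'
#' @param n_burnin Burn-in sweeps.
#' @param n_iter Post-burn-in sweeps.
#' @param thin Keep every `thin`-th sweep.
#' @param lambda Dirichlet concentration for allele frequencies under the
#'   independent-frequencies model (default 1, uniform).
#' @param alpha_init,alpha_max,alpha_sd Admixture hyperparameter alpha:
#'   initial value, upper bound of its flat prior, and random-walk Metropolis
#'   proposal SD.
#' @param update_alpha If `FALSE`, alpha stays fixed at `alpha_init`
#'   (used for exact-oracle comparisons).
#' @param seed Integer seed.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burnin = 5000, n_iter = 20000, thin = 10,
                        lambda = 1.0, alpha_init = 1.0, alpha_max = 10.0,
                        alpha_sd = 0.025, update_alpha = TRUE, seed = 1) {
  stopifnot(n_burnin >= 1, n_iter >= 1, thin >= 1, lambda > 0,
            alpha_init > 0, alpha_max >= alpha_init, alpha_sd >= 0)
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), k = 2L, lambda = lambda,
                 alpha_init = alpha_init, alpha_max = alpha_max,
                 alpha_sd = alpha_sd, update_alpha = isTRUE(update_alpha),
                 seed = seed),
            class = "mcmc_config")
}

# recode alleles per locus to 0..(J_l - 1); support = union observed in the
# table (optionally extended by an allele_freqs support)
recode_alleles <- function(table, freqs = NULL) {
  L <- n_loci(table)
  geno <- matrix(NA_integer_, n_individuals(table), 2L * L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    cols <- c(2L * l - 1L, 2L * l)
    obs <- as.vector(table$alleles[, cols, drop = FALSE])
    support <- sort(unique(obs[!is.na(obs)]))
    if (!is.null(freqs)) {
      support <- sort(unique(c(support, as.integer(colnames(freqs$freqs[[l]])))))
    }
    if (length(support) == 0L) stop("locus ", table$panel[l], " entirely missing")
    n_alleles[l] <- length(support)
    geno[, cols] <- match(table$alleles[, cols, drop = FALSE], support) - 1L
  }
  list(geno = geno, n_alleles = n_alleles)
}

#' Fit the K = 2 Bayesian admixture model
#'
#' Gibbs sampler for the standard admixture model with independent allele
#' frequencies: each allele copy has a latent cluster of origin drawn from
#' the individual's membership vector q_i, cluster allele frequencies have a
#' Dirichlet(lambda) prior, q_i has a symmetric Dirichlet(alpha) prior, and
#' alpha is learned by random-walk Metropolis under a flat prior on
#' (0, alpha_max]. Missing loci contribute nothing to the likelihood. The
#' run is unsupervised: no prior population information is used, and cluster
#' labels are anchored afterwards with [align_clusters()].
#'
#' @param table A `genotype_table` with at least two individuals.
#' @param config An [mcmc_config()].
#' @return An object of class `admixture_fit` holding thinned post-burn-in
#'   posterior samples of each individual's membership to cluster 1
#'   (`q_samples`, iterations x individuals), alpha samples, ids, labels and
#'   the configuration. Use [align_clusters()] then [summarize_q()].
#' @seealso [assign_one_by_one()] for the one-query-at-a-time protocol.
#' @export
admixture_fit <- function(table, config = mcmc_config()) {
  stopifnot(inherits(table, "genotype_table"), inherits(config, "mcmc_config"))
  rc <- recode_alleles(table)
  res <- .admix_gibbs_cpp(rc$geno, rc$n_alleles,
                          config$n_burnin, config$n_iter, config$thin,
                          config$lambda, config$alpha_init, config$alpha_max,
                          config$alpha_sd, config$update_alpha,
                          as.double(config$seed))
  colnames(res$q) <- table$ids
  structure(list(q_samples = res$q, alpha_samples = res$alpha,
                 ids = table$ids, labels = table$labels,
                 aligned = FALSE, config = config),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit (K = 2): %d individuals, %d retained samples%s\n",
              length(x$ids), nrow(x$q_samples),
              if (x$aligned) ", clusters aligned to wild anchor" else ""))
  cat(sprintf("chain: %d burn-in + %d sweeps, thin %d; mean alpha = %.3f\n",
              x$config$n_burnin, x$config$n_iter, x$config$thin,
              mean(x$alpha_samples)))
  invisible(x)
}

#' @export
coef.admixture_fit <- function(object, ...) {
  q <- colMeans(object$q_samples)
  cbind(q_wild = q, q_dom = 1 - q)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  summarize_q(object)
}

#' Anchor admixture clusters to the wild reference pool
#'
#' Resolves the label-switching symmetry of the K = 2 model: cluster labels
#' are permuted so that the mean membership of the wild reference
#' individuals to the "wild" cluster exceeds 0.5. The permutation is applied
#' per retained sample (a sample whose wild-reference mean falls below 0.5 is
#' flipped), which coincides with a single whole-run flip on well-separated
#' data but also relabels correctly when a small problem lets the chain
#' traverse both label modes. Errors if no sample provides an anchor
#' (a degenerate run).
#'
#' @param fit An `admixture_fit`.
#' @param wild_ids Ids (or a logical/integer index over the fit's
#'   individuals) of the wild reference individuals.
#' @return The fit with cluster 1 guaranteed to be the wild cluster.
#' @export
align_clusters <- function(fit, wild_ids) {
  stopifnot(inherits(fit, "admixture_fit"))
  if (is.character(wild_ids)) {
    idx <- match(wild_ids, fit$ids)
    if (anyNA(idx)) stop("unknown wild reference id")
  } else {
    idx <- wild_ids
  }
  anchor <- rowMeans(fit$q_samples[, idx, drop = FALSE])
  if (all(anchor == 0.5)) {
    stop("degenerate run: wild references load equally on both clusters")
  }
  flip <- anchor < 0.5
  if (any(flip)) fit$q_samples[flip, ] <- 1 - fit$q_samples[flip, ]
  fit$aligned <- TRUE
  fit
}

#' Posterior summaries of individual membership coefficients
#'
#' @param fit An aligned `admixture_fit`.
#' @param ids Individuals to summarize (default: all).
#' @return Data frame with posterior mean wild membership (`q_wild_mean`),
#'   its equal-tailed 90% credibility interval (5th/95th posterior
#'   percentiles of thinned draws, widened minimally if needed so the bounds
#'   always bracket the mean, which matters only for posteriors piled against
#'   0 or 1), the complementary domestic membership, and sampling provenance.
#' @export
summarize_q <- function(fit, ids = fit$ids) {
  stopifnot(inherits(fit, "admixture_fit"))
  idx <- match(ids, fit$ids)
  if (anyNA(idx)) stop("unknown individual id")
  qs <- fit$q_samples[, idx, drop = FALSE]
  ci <- apply(qs, 2L, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
  data.frame(
    individual_id = fit$ids[idx],
    label = fit$labels[idx],
    q_wild_mean = colMeans(qs),
    q_wild_lo90 = pmin(ci[1L, ], colMeans(qs)),
    q_wild_hi90 = pmax(ci[2L, ], colMeans(qs)),
    q_dom_mean = 1 - colMeans(qs),
    n_samples_kept = nrow(qs),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Assign query genotypes one by one against reference populations
#'
#' The one-by-one protocol: each query individual is analysed in its own
#' K = 2 admixture run containing all reference individuals plus that single
#' query, so that sample sizes and the presence of other admixed genotypes
#' cannot affect its assignment. Runs are mutually independent (per-query
#' seeds are derived deterministically from `config$seed` and the query's
#' id, so results do not depend on query order) and each run is anchored to
#' the wild references before summarizing.
#'
#' @param references A `genotype_table` containing both reference pools.
#' @param queries A `genotype_table` of individuals to assign.
#' @param config An [mcmc_config()]; `config$seed` seeds the whole set.
#' @param wild_labels Labels identifying wild reference individuals inside
#'   `references` (used for cluster anchoring).
#' @param keep_draws Keep each query's thinned posterior draws (needed for
#'   group-level credibility intervals); default `TRUE`.
#' @return An `assignment_set`: a data frame with one row per query
#'   (`individual_id`, `label`, `q_wild_mean`, `q_wild_lo90`, `q_wild_hi90`,
#'   `q_dom_mean`, `n_samples_kept`, `seed`), with the per-query posterior
#'   draws in `attr(, "draws")` when `keep_draws` is `TRUE`.
#' @export
assign_one_by_one <- function(references, queries, config = mcmc_config(),
                              wild_labels = c("RW", "wild"),
                              keep_draws = TRUE) {
  stopifnot(inherits(references, "genotype_table"),
            inherits(queries, "genotype_table"))
  if (!identical(references$panel, queries$panel)) {
    stop("references and queries do not share a panel")
  }
  if (n_individuals(queries) == 0L) stop("no query individuals")
  wild_ids <- references$ids[references$labels %in% wild_labels]
  if (length(wild_ids) == 0L) {
    stop("no wild reference individuals with labels: ",
         paste(wild_labels, collapse = ", "))
  }
  if (any(queries$ids %in% references$ids)) {
    stop("query ids overlap reference ids")
  }
  rows <- vector("list", n_individuals(queries))
  draws <- if (keep_draws) {
    matrix(NA_real_, config$n_iter %/% config$thin, n_individuals(queries),
           dimnames = list(NULL, queries$ids))
  }
  for (j in seq_len(n_individuals(queries))) {
    qj <- queries[j]
    seed_j <- derive_seed(config$seed, qj$ids)
    cfg_j <- config
    cfg_j$seed <- seed_j
    fit <- admixture_fit(rbind_genotypes(references, qj), cfg_j)
    fit <- align_clusters(fit, wild_ids)
    s <- summarize_q(fit, ids = qj$ids)
    s$seed <- seed_j
    rows[[j]] <- s
    if (keep_draws) draws[, j] <- fit$q_samples[, n_individuals(references) + 1L]
  }
  out <- do.call(rbind, rows)
  class(out) <- c("assignment_set", "data.frame")
  if (keep_draws) attr(out, "draws") <- draws
  out
}

#' @export
print.assignment_set <- function(x, ...) {
  cat(sprintf("assignment_set: %d individuals (one-by-one K = 2 admixture)\n",
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Box plot of wild membership by class
#'
#' @param x An `assignment_set`.
#' @param thresholds Optional [threshold_pair()] drawn as horizontal lines.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.assignment_set <- function(x, thresholds = NULL, ...) {
  lv <- intersect(c(cross_classes(), unique(x$label)), unique(x$label))
  graphics::boxplot(q_wild_mean ~ factor(label, levels = lv),
                    data = as.data.frame(x),
                    xlab = "class", ylab = expression(q[wild]), ...)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$t_recent, lty = 2)
    graphics::abline(h = thresholds$t_pure, col = 2)
  }
  invisible(x)
}

#' Group-level membership summaries
#'
#' Averages individual membership coefficients within predefined groups and
#' attaches a 90% spread obtained from the pooled posterior draws of the
#' group's individuals.
#'
#' @param results An `assignment_set` (with draws kept) or a data frame with
#'   `individual_id` and `q_wild_mean`.
#' @param labels Optional grouping vector overriding `results$label`.
#' @return Data frame with one row per group: mean wild/domestic membership
#'   and the 5th/95th percentiles of pooled draws (or of individual means
#'   when draws are unavailable).
#' @export
summarize_groups <- function(results, labels = results$label) {
  if (length(labels) != nrow(results)) stop("grouping length mismatch")
  if (any(is.na(labels))) stop("every individual must be labelled")
  draws <- attr(results, "draws")
  groups <- unique(labels)
  out <- lapply(groups, function(g) {
    sel <- which(labels == g)
    if (length(sel) == 0L) stop("empty group: ", g)
    pooled <- if (!is.null(draws)) as.vector(draws[, sel, drop = FALSE])
              else results$q_wild_mean[sel]
    ci <- stats::quantile(pooled, c(0.05, 0.95), names = FALSE)
    data.frame(label = g, n = length(sel),
               Q_wild_mean = mean(results$q_wild_mean[sel]),
               Q_wild_lo90 = ci[1L], Q_wild_hi90 = ci[2L],
               Q_dom_mean = 1 - mean(results$q_wild_mean[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Between-run stability of membership coefficients
#'
#' Mean and SD of the absolute difference in wild membership across all
#' individuals and all pairs of independent runs — the statistic used to
#' decide whether multi-run averaging is needed.
#'
#' @param ... Two or more `assignment_set`s (or named q vectors) over the
#'   same individuals.
#' @return Named numeric vector `c(mean, sd)` of absolute q differences.
#' @export
run_stability <- function(...) {
  runs <- lapply(list(...), as_q_vector)
  if (length(runs) < 2L) stop("need at least two runs")
  ids <- names(runs[[1L]])
  for (r in runs) {
    if (!setequal(names(r), ids)) stop("runs cover different individuals")
  }
  diffs <- c()
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i < j) diffs <- c(diffs, abs(runs[[i]][ids] - runs[[j]][ids]))
    }
  }
  c(mean = mean(diffs), sd = stats::sd(diffs))
}
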