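#' Construct a multilocus genotype table
#'
#' The central data container: diploid, integer-coded genotypes at a panel of
#' codominant loci (typically microsatellites), one row per individual with a
#' class or population label. Missing data are per locus: both allele copies
#' are absent together, the usual situation when a microsatellite locus fails
#' to amplify.
#'
#' @param ids Character vector of unique individual identifiers.
#' @param labels Character vector of class/population labels (e.g. "RW", "RD",
#'   "PW", "F1", "BC1W", "QUERY"), one per individual.
#' @param alleles Integer matrix with one row per individual and two columns
#'   per locus (locus-major order: locus 1 copy 1, locus 1 copy 2, locus 2
#'   copy 1, ...). Allele codes are positive integers; missing calls are `NA`
#'   in both columns of the locus.
#' @param panel Character vector of unique locus names, one per locus.
#' @return An object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(
#'   ids = c("W01", "D01"), labels = c("RW", "RD"),
#'   alleles = rbind(c(132L, 136L, NA, NA), c(140L, 140L, 98L, 102L)),
#'   panel = c("FH2004", "FH2088")
#' )
#' gt
#' @export
genotype_table <- function(ids, labels, alleles, panel) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  panel <- as.character(panel)
  if (anyDuplicated(panel)) stop("locus names must be unique")
  if (length(panel) < 1L) stop("panel must contain at least one locus")
  if (!is.matrix(alleles)) alleles <- matrix(alleles, nrow = length(ids))
  storage.mode(alleles) <- "integer"
  n <- length(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(labels) != n) stop("labels must match number of individuals")
  if (nrow(alleles) != n || ncol(alleles) != 2L * length(panel)) {
    stop("allele matrix must be n x 2*n_loci")
  }
  obs <- alleles[, seq(1L, ncol(alleles), by = 2L), drop = FALSE]
  obs2 <- alleles[, seq(2L, ncol(alleles), by = 2L), drop = FALSE]
  if (any(is.na(obs) != is.na(obs2))) {
    stop("both allele copies at a locus must be missing together")
  }
  if (any(alleles <= 0L, na.rm = TRUE)) stop("allele codes must be positive integers")
  structure(
    list(ids = ids, labels = labels, alleles = alleles, panel = panel),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d loci\n",
    n_individuals(x), n_loci(x)
  ))
  tab <- table(x$labels)
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param x A `genotype_table`.
#' @return Integer count.
#' @export
n_individuals <- function(x) length(x$ids)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$panel)

#' Subset individuals of a genotype table
#' @param x A `genotype_table`.
#' @param i Index vector (logical, integer, or individual ids).
#' @param ... Unused.
#' @return A `genotype_table` with the selected rows.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$ids)
    if (anyNA(i)) stop("unknown individual id")
  }
  genotype_table(x$ids[i], x$labels[i], x$alleles[i, , drop = FALSE], x$panel)
}

#' Combine genotype tables sharing a panel
#' @param ... `genotype_table` objects with identical panels.
#' @return A single `genotype_table`.
#' @export
rbind_genotypes <- function(...) {
  tabs <- list(...)
  panel <- tabs[[1L]]$panel
  for (t in tabs) {
    if (!identical(t$panel, panel)) stop("tables do not share a panel")
  }
  genotype_table(
    unlist(lapply(tabs, `[[`, "ids")),
    unlist(lapply(tabs, `[[`, "labels")),
    do.call(rbind, lapply(tabs, `[[`, "alleles")),
    panel
  )
}

#' @export
as.data.frame.genotype_table <- function(x, ...) {
  df <- as.data.frame(x$alleles)
  names(df) <- paste0(rep(x$panel, each = 2L), c("_1", "_2"))
  cbind(data.frame(individual_id = x$ids, label = x$labels,
                   stringsAsFactors = FALSE), df)
}

#' Read a genotype table in the one-row-per-individual Structure dialect
#'
#' The file is whitespace-delimited with one row per individual: individual
#' id, label, then two integer allele columns per locus. Missing loci carry
#' the sentinel `-9` in both columns.
#'
#' @param path Path to the file.
#' @param panel Character vector of locus names defining the expected panel.
#' @return A `genotype_table`.
#' @seealso [write_structure_table()]
#' @export
read_structure_table <- function(path, panel) {
  panel <- as.character(panel)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(genotype_table(character(), character(),
                          matrix(integer(), 0L, 2L * length(panel)), panel))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  want <- 2L + 2L * length(panel)
  ids <- character(length(fields))
  labels <- character(length(fields))
  alleles <- matrix(NA_integer_, length(fields), 2L * length(panel))
  for (r in seq_along(fields)) {
    f <- fields[[r]]
    if (length(f) != want) {
      stop(sprintf("line %d: expected %d fields, found %d", r, want, length(f)))
    }
    ids[r] <- f[1L]
    labels[r] <- f[2L]
    a <- suppressWarnings(as.integer(f[-(1:2)]))
    bad <- which(is.na(a) | suppressWarnings(as.numeric(f[-(1:2)])) != a)
    if (length(bad) > 0L) {
      stop(sprintf("line %d: non-integer allele code '%s'", r, f[-(1:2)][bad[1L]]))
    }
    a[a == -9L] <- NA_integer_
    alleles[r, ] <- a
  }
  genotype_table(ids, labels, alleles, panel)
}

#' Write a genotype table in the one-row-per-individual Structure dialect
#'
#' Missing loci are written as `-9` in both allele columns. Reading the file
#' back with [read_structure_table()] and the same panel reproduces the table
#' exactly.
#'
#' @param table A `genotype_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure_table <- function(table, path) {
  a <- table$alleles
  a[is.na(a)] <- -9L
  rows <- apply(cbind(table$ids, table$labels, a), 1L, paste, collapse = " ")
  writeLines(as.character(rows), path)
  invisible(path)
}

#' Restrict a genotype table to a subset of loci
#'
#' Used to move between a full marker panel and a reduced one (e.g. a 12-STR
#' subset of a 39-STR panel used for low-content DNA samples).
#'
#' @param table A `genotype_table`.
#' @param keep Character vector of locus names to retain, in the desired order.
#' @return A `genotype_table` restricted (and reordered) to `keep`.
#' @export
subset_panel <- function(table, keep) {
  keep <- as.character(keep)
  idx <- match(keep, table$panel)
  if (anyNA(idx)) {
    stop("unknown locus name(s): ", paste(keep[is.na(idx)], collapse = ", "))
  }
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  genotype_table(table$ids, table$labels,
                 table$alleles[, cols, drop = FALSE], keep)
}

#' Drop individuals with too much missing data
#'
#' Retains individuals whose fraction of missing loci is strictly below
#' `max_missing_fraction`, mirroring the quality rule that genotypes are
#' reliable only when dropout/missingness stays under a fixed proportion.
#'
#' @param table A `genotype_table`.
#' @param max_missing_fraction Proportion in `[0, 1]`; individuals with a
#'   missing-locus fraction `>=` this value are removed.
#' @return The filtered `genotype_table`; surviving genotypes are unchanged.
#' @export
qc_filter_genotypes <- function(table, max_missing_fraction = 0.10) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  first <- table$alleles[, seq(1L, ncol(table$alleles), by = 2L), drop = FALSE]
  frac <- rowMeans(is.na(first))
  table[frac < max_missing_fraction]
}

#' Select reference candidates by membership coefficient and completeness
#'
#' Reference parental individuals are retained only if their genotype has no
#' missing loci and their membership to their nominal cluster exceeds
#' `min_q` (0.990 by default), a conservative rule that keeps older admixed
#' animals out of the reference pools.
#'
#' @param table A `genotype_table` of candidate reference individuals.
#' @param q_values Named numeric vector: membership coefficient of each
#'   individual to its own nominal cluster; names are individual ids.
#' @param min_q Minimum membership, in `(0.5, 1]`.
#' @return The filtered `genotype_table`.
#' @export
filter_reference_candidates <- function(table, q_values, min_q = 0.990) {
  stopifnot(min_q > 0.5, min_q <= 1)
  q <- q_values[table$ids]
  if (anyNA(q)) {
    stop("missing q value for individual(s): ",
         paste(table$ids[is.na(q)], collapse = ", "))
  }
  first <- table$alleles[, seq(1L, ncol(table$alleles), by = 2L), drop = FALSE]
  complete <- rowSums(is.na(first)) == 0L
  table[complete & q > min_q]
}

#' Estimate per-group allele frequencies
#'
#' Plain counting estimator: the frequency of allele j in a group at a locus
#' is its count among non-missing allele copies divided by the number of
#' non-missing copies. Allele support is harmonized across groups at each
#' locus (union of observed alleles, zero frequency where unobserved).
#'
#' @param table A `genotype_table`.
#' @param by Grouping vector (defaults to the table's labels).
#' @return An `allele_freqs` object: per locus, a groups x alleles frequency
#'   matrix whose rows sum to one.
#' @export
estimate_allele_frequencies <- function(table, by = table$labels) {
  by <- as.character(by)
  if (length(by) != n_individuals(table)) stop("grouping length mismatch")
  groups <- unique(by)
  freqs <- vector("list", n_loci(table))
  names(freqs) <- table$panel
  for (l in seq_len(n_loci(table))) {
    copies <- table$alleles[, c(2L * l - 1L, 2L * l), drop = FALSE]
    support <- sort(unique(as.vector(copies[!is.na(copies)])))
    if (length(support) == 0L) stop("locus ", table$panel[l], " has no observed alleles")
    mat <- matrix(0, length(groups), length(support),
                  dimnames = list(groups, as.character(support)))
    for (g in groups) {
      obs <- as.vector(copies[by == g, , drop = FALSE])
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) {
        stop(sprintf("locus %s has no non-missing copies in group %s",
                     table$panel[l], g))
      }
      cnt <- table(factor(as.character(obs), levels = as.character(support)))
      mat[g, ] <- as.numeric(cnt) / length(obs)
    }
    freqs[[l]] <- mat
  }
  allele_freqs(freqs, groups)
}

#' Allele-frequency set constructor
#'
#' @param freqs Named list (one element per locus) of groups x alleles
#'   frequency matrices; column names are allele codes.
#' @param groups Character vector of group (population) names.
#' @return An `allele_freqs` object.
#' @export
allele_freqs <- function(freqs, groups) {
  groups <- as.character(groups)
  for (l in seq_along(freqs)) {
    m <- freqs[[l]]
    if (!all(rownames(m) == groups)) stop("group rows inconsistent across loci")
    if (any(m < 0)) stop("negative frequency")
    if (any(abs(rowSums(m) - 1) > 1e-9)) stop("frequency rows must sum to 1")
  }
  structure(list(freqs = freqs, groups = groups, panel = names(freqs)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele_freqs: %d loci, groups: %s\n",
              length(x$freqs), paste(x$groups, collapse = ", ")))
  na <- vapply(x$freqs, ncol, 1L)
  cat(sprintf("alleles per locus: %d-%d (mean %.1f)\n",
              min(na), max(na), mean(na)))
  invisible(x)
}
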