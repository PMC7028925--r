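#' The candidate q-threshold grid
#'
#' Thresholds from 0.500 to 0.995 in steps of 0.005, plus the terminal value
#' 0.999 (101 values in total).
#'
#' @return Numeric vector of candidate thresholds.
#' @export
threshold_grid <- function() {
  c(round(seq(0.500, 0.995, by = 0.005), 3), 0.999)
}

#' Ladder order of the wild-side classes
#'
#' Classes ordered by increasing admixture: PW, BC8W, ..., BC1W, F2, F1.
#' The domestic parental class takes no part in wild-side threshold analysis.
#'
#' @return Character vector of class names in ladder order.
#' @export
ladder_classes <- function() {
  c("PW", paste0("BC", 8:1, "W"), "F2", "F1")
}

#' Enumerate nested pure/admixed splits along the admixture ladder
#'
#' Generates the nested family of class splits tested during threshold
#' selection: the pure side starts as `{PW}` and grows one backcross
#' generation at a time, up to `{PW, BC8W, ..., BC2W}`; the admixed side is
#' the complement. F1, F2 and BC1W are never placed on the pure side.
#'
#' @param classes Ladder-ordered class vector (default [ladder_classes()]).
#' @return List of splits, each a list with `name`, `pure` and `admixed`.
#' @export
enumerate_splits <- function(classes = ladder_classes()) {
  n_pure_max <- length(classes) - 3L   # keep BC1W, F2, F1 always admixed
  lapply(seq_len(n_pure_max), function(i) {
    pure <- classes[seq_len(i)]
    admixed <- setdiff(classes, pure)
    list(name = sprintf("%s | %s", paste(pure, collapse = "+"),
                        paste(admixed, collapse = "+")),
         pure = pure, admixed = admixed)
  })
}

#' Efficiency and accuracy of a q-threshold for one split
#'
#' Individuals are called admixed when their wild membership `q < t`.
#' Under the default one-sided reading, efficiency is the proportion of truly
#' admixed individuals (per the split) correctly identified (sensitivity)
#' and accuracy is the proportion of individuals called admixed that truly
#' are (positive predictive value); when nothing falls below `t`, accuracy is
#' vacuously 1. The `"two_sided"` mode averages each quantity over the
#' admixed and pure sides symmetrically.
#'
#' @param q Numeric vector of wild membership coefficients.
#' @param labels Class label per individual.
#' @param split One element of [enumerate_splits()].
#' @param t Candidate threshold.
#' @param mode `"one_sided"` (default) or `"two_sided"`.
#' @return Named vector `c(efficiency, accuracy)`.
#' @export
efficiency_accuracy <- function(q, labels, split, t,
                                mode = c("one_sided", "two_sided")) {
  mode <- match.arg(mode)
  sel <- labels %in% c(split$pure, split$admixed)
  q <- q[sel]
  labels <- labels[sel]
  truth_adm <- labels %in% split$admixed
  if (!any(truth_adm)) stop("split has no admixed individuals in the data")
  called_adm <- q < t
  tp <- sum(truth_adm & called_adm)
  eff <- tp / sum(truth_adm)
  acc <- if (sum(called_adm) == 0L) 1 else tp / sum(called_adm)
  if (mode == "two_sided") {
    tn <- sum(!truth_adm & !called_adm)
    eff_pure <- if (any(!truth_adm)) tn / sum(!truth_adm) else 1
    acc_pure <- if (sum(!called_adm) == 0L) 1 else tn / sum(!called_adm)
    eff <- (eff + eff_pure) / 2
    acc <- (acc + acc_pure) / 2
  }
  c(efficiency = eff, accuracy = acc)
}

#' Performance of every (threshold, split) combination
#'
#' Performance is the product efficiency x accuracy, computed for every
#' candidate threshold and every nested class split.
#'
#' @inheritParams efficiency_accuracy
#' @param splits List of splits (default [enumerate_splits()]).
#' @param thresholds Candidate thresholds (default [threshold_grid()]).
#' @return A data frame of class `performance_grid` with columns `threshold`,
#'   `split`, `efficiency`, `accuracy`, `performance`.
#' @export
performance_grid <- function(q, labels, splits = enumerate_splits(),
                             thresholds = threshold_grid(),
                             mode = c("one_sided", "two_sided")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(splits), function(s) {
    ea <- vapply(thresholds, function(t) {
      efficiency_accuracy(q, labels, splits[[s]], t, mode = mode)
    }, numeric(2))
    data.frame(threshold = thresholds,
               split = splits[[s]]$name,
               split_index = s,
               efficiency = ea[1L, ],
               accuracy = ea[2L, ],
               performance = ea[1L, ] * ea[2L, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_grid", "data.frame")
  out
}

#' @export
plot.performance_grid <- function(x, ...) {
  splits <- unique(x$split_index)
  graphics::plot(NULL, xlim = range(x$threshold), ylim = c(0, 1),
                 xlab = "q-threshold", ylab = "performance", ...)
  for (s in splits) {
    d <- x[x$split_index == s, ]
    graphics::lines(d$threshold, d$performance, col = s)
  }
  invisible(x)
}

#' Select the recent-admixture q-threshold from a performance grid
#'
#' Splits whose best performance reaches `min_performance` are retained; the
#' conservative choice is then the highest threshold attaining any retained
#' split's maximum performance (ties within a split's maximum-performance
#' plateau resolve to the plateau's highest threshold).
#'
#' @param grid A [performance_grid()].
#' @param min_performance Minimum best performance for a split to be retained
#'   (default 0.90).
#' @return The selected threshold, with attributes `split` (the split it came
#'   from) and `performance` (that split's best performance).
#' @export
select_recent_threshold <- function(grid, min_performance = 0.90) {
  best_t <- c()
  best_perf <- c()
  split_names <- c()
  for (s in unique(grid$split_index)) {
    d <- grid[grid$split_index == s, ]
    mx <- max(d$performance)
    if (mx >= min_performance) {
      plateau <- d$threshold[d$performance >= mx - 1e-12]
      best_t <- c(best_t, max(plateau))
      best_perf <- c(best_perf, mx)
      split_names <- c(split_names, d$split[1L])
    }
  }
  if (length(best_t) == 0L) {
    stop("no split reaches the minimum performance of ", min_performance,
         "; the marker panel is likely too weak - consider more markers")
  }
  i <- which.max(best_t)
  structure(best_t[i], split = split_names[i], performance = best_perf[i])
}

#' Select the pure q-threshold from the wild parental distribution
#'
#' The pure threshold is the minimum individual wild membership observed
#' among reference and simulated wild parentals, rounded down to three
#' decimals so the defining individual still satisfies `q >= t_pure`.
#'
#' @param q Numeric vector of wild membership coefficients.
#' @param labels Class label per individual.
#' @param wild_parental_labels Labels treated as wild parentals.
#' @return The pure threshold.
#' @export
select_pure_threshold <- function(q, labels,
                                  wild_parental_labels = c("RW", "PW")) {
  sel <- labels %in% wild_parental_labels
  if (!any(sel)) stop("no wild parental individuals found")
  floor(min(q[sel]) * 1000) / 1000
}

#' Bundle the two selected q-thresholds
#'
#' @param t_recent Threshold separating recent admixed individuals.
#' @param t_pure Threshold separating pure individuals; must satisfy
#'   `0.5 < t_recent < t_pure <= 1`.
#' @return A list of class `threshold_pair`.
#' @export
threshold_pair <- function(t_recent, t_pure) {
  t_recent <- as.numeric(t_recent)
  t_pure <- as.numeric(t_pure)
  if (!(t_recent > 0.5 && t_recent < t_pure && t_pure <= 1)) {
    stop("invalid thresholds: need 0.5 < t_recent < t_pure <= 1 (got ",
         t_recent, ", ", t_pure, ")")
  }
  structure(list(t_recent = t_recent, t_pure = t_pure),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("q-thresholds: recent admixture < %.3f <= older admixture < %.3f <= pure\n",
              x$t_recent, x$t_pure))
  invisible(x)
}

assignment_class_levels <- function() {
  c("recent admixed", "older admixed", "pure")
}

management_category_levels <- function() {
  c("operational hybrid", "introgressed", "operational pure")
}

#' Classify individuals into assignment classes and management categories
#'
#' Three-way classification on the posterior mean wild membership:
#' `q >= t_pure` is pure (operational pure individual, no action);
#' `t_recent <= q < t_pure` is older admixed (introgressed individual, low
#' priority); `q < t_recent` is recent admixed (operational hybrid, high
#' priority). Boundary values belong to the upper class.
#'
#' @param q Numeric vector of wild membership coefficients, or an
#'   `assignment_set`.
#' @param thresholds A [threshold_pair()].
#' @return Data frame with `q_wild`, `assignment_class` and
#'   `management_category` (ordered factors, hybrid < introgressed < pure),
#'   plus ids/labels when an `assignment_set` is supplied.
#' @export
classify_individuals <- function(q, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  base <- NULL
  if (inherits(q, "assignment_set") || is.data.frame(q)) {
    base <- data.frame(individual_id = q$individual_id, label = q$label,
                       stringsAsFactors = FALSE)
    q <- q$q_wild_mean
  }
  idx <- ifelse(q >= thresholds$t_pure, 3L,
                ifelse(q >= thresholds$t_recent, 2L, 1L))
  out <- data.frame(
    q_wild = q,
    assignment_class = factor(assignment_class_levels()[idx],
                              levels = assignment_class_levels(),
                              ordered = TRUE),
    management_category = factor(management_category_levels()[idx],
                                 levels = management_category_levels(),
                                 ordered = TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(base)) out <- cbind(base, out)
  out
}

#' Type I / type II error rates of a classification
#'
#' Type I error: truly pure individuals (wild parentals) classified as
#' anything but pure. Type II error: truly admixed individuals (F1 through
#' BC8W) classified as pure. Also returns the per-class confusion table of
#' category percentages.
#'
#' @param classified Output of [classify_individuals()] including `label`.
#' @param pure_labels True-pure class labels.
#' @param admixed_labels True-admixed class labels.
#' @return List with `type_I`, `type_II` and `confusion` (classes x
#'   categories, row percentages).
#' @export
error_rates <- function(classified,
                        pure_labels = c("RW", "PW"),
                        admixed_labels = c("F1", "F2", paste0("BC", 1:8, "W"))) {
  stopifnot(all(c("label", "management_category") %in% names(classified)))
  is_pure_truth <- classified$label %in% pure_labels
  is_adm_truth <- classified$label %in% admixed_labels
  called_pure <- classified$management_category == "operational pure"
  type_I <- if (any(is_pure_truth)) mean(!called_pure[is_pure_truth]) else NA_real_
  type_II <- if (any(is_adm_truth)) mean(called_pure[is_adm_truth]) else NA_real_
  conf <- 100 * prop.table(
    table(class = classified$label, category = classified$management_category),
    margin = 1L
  )
  list(type_I = type_I, type_II = type_II, confusion = conf)
}
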