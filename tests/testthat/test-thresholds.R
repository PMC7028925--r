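test_that("the candidate grid spans 0.500-0.999 in 101 steps", {
  g <- threshold_grid()
  expect_length(g, 101L)
  expect_equal(g[1], 0.5)
  expect_equal(g[length(g)], 0.999)
  expect_equal(unique(round(diff(g)[1:99], 10)), 0.005)
})

test_that("nested splits grow the pure side one class at a time", {
  sp <- enumerate_splits()
  expect_length(sp, 8L)
  expect_equal(sp[[1]]$pure, "PW")
  expect_equal(sp[[1]]$admixed, c(paste0("BC", 8:1, "W"), "F2", "F1"))
  expect_equal(sp[[8]]$pure, c("PW", paste0("BC", 8:2, "W")))
  expect_equal(sp[[8]]$admixed, c("BC1W", "F2", "F1"))
  for (s in sp) {
    expect_false("F1" %in% s$pure)
    expect_false("F2" %in% s$pure)
    expect_false("BC1W" %in% s$pure)
    expect_length(intersect(s$pure, s$admixed), 0L)
  }
})

test_that("efficiency and accuracy follow the confusion-table definitions", {
  # 10 true admixed with 8 below t, 2 pure below t
  q <- c(rep(0.4, 8), rep(0.99, 2),   # admixed: 8 detected, 2 missed
         rep(0.4, 2), rep(0.99, 8))   # pure: 2 false positives
  labels <- c(rep("F1", 10), rep("PW", 10))
  split <- list(name = "PW | F1", pure = "PW", admixed = "F1")
  ea <- efficiency_accuracy(q, labels, split, 0.955)
  expect_equal(unname(ea), c(0.8, 0.8))
  expect_equal(unname(prod(ea)), 0.64)
  # perfect separation
  ea2 <- efficiency_accuracy(c(0.3, 0.3, 0.99, 0.99),
                             c("F1", "F1", "PW", "PW"), split, 0.9)
  expect_equal(unname(ea2), c(1, 1))
  # nothing called admixed: efficiency 0, vacuous accuracy 1
  ea3 <- efficiency_accuracy(c(0.9, 0.9), c("F1", "PW"), split, 0.5)
  expect_equal(unname(ea3), c(0, 1))
  expect_error(efficiency_accuracy(0.9, "PW", split, 0.9), "no admixed")
})

test_that("grid cells agree with brute-force confusion tables", {
  # property check over 1000 random labelled q tables
  set.seed(99)
  split <- list(name = "s", pure = c("PW", "BC8W"), admixed = c("F1", "F2"))
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    labels <- sample(c("PW", "BC8W", "F1", "F2"), n, replace = TRUE)
    if (!any(labels %in% split$admixed)) next
    q <- round(stats::runif(n), 2)
    t <- sample(threshold_grid(), 1)
    ea <- efficiency_accuracy(q, labels, split, t)
    # brute force
    truth <- labels %in% c("F1", "F2")
    called <- q < t
    tp <- sum(truth & called); fn <- sum(truth & !called)
    fp <- sum(!truth & called)
    expect_identical(unname(ea[1]), tp / (tp + fn))
    expect_identical(unname(ea[2]), if (tp + fp == 0) 1 else tp / (tp + fp))
  }
})

test_that("performance grid is the efficiency-accuracy product", {
  q <- c(0.3, 0.5, 0.97, 0.99, 0.999, 0.96, 0.7)
  labels <- c("F1", "F1", "BC8W", "PW", "PW", "BC2W", "BC1W")
  grid <- performance_grid(q, labels)
  expect_equal(nrow(grid), 101L * 8L)
  expect_equal(grid$performance, grid$efficiency * grid$accuracy)
  expect_true(all(grid$performance <= pmin(grid$efficiency, grid$accuracy) + 1e-12))
  expect_true(all(grid$performance >= 0 & grid$performance <= 1))
})

test_that("recent-threshold selection retains the highest performing threshold", {
  # synthetic grid reproducing the published three-split outcome:
  # maxima 0.982 @ 0.670, 0.922 @ 0.840, 0.900 @ plateau 0.950-0.955
  g <- threshold_grid()
  mk <- function(idx, peak_t, peak_p, plateau = peak_t) {
    perf <- pmax(0, peak_p - 2 * abs(g - peak_t))
    perf[g >= peak_t & g <= plateau] <- peak_p
    data.frame(threshold = g, split = paste0("S", idx), split_index = idx,
               efficiency = perf, accuracy = 1, performance = perf)
  }
  grid <- rbind(mk(1, 0.670, 0.982), mk(2, 0.840, 0.922),
                mk(3, 0.950, 0.900, plateau = 0.955),
                mk(4, 0.990, 0.80))
  class(grid) <- c("performance_grid", "data.frame")
  t_recent <- select_recent_threshold(grid, 0.90)
  expect_equal(as.numeric(t_recent), 0.955)
  expect_equal(attr(t_recent, "performance"), 0.900)
  # single split with a plateau resolves to the plateau's top
  solo <- mk(1, 0.90, 0.95, plateau = 0.92)
  class(solo) <- c("performance_grid", "data.frame")
  expect_equal(as.numeric(select_recent_threshold(solo)), 0.92)
  # nothing retained -> error recommending more markers
  weak <- mk(1, 0.8, 0.5)
  class(weak) <- c("performance_grid", "data.frame")
  expect_error(select_recent_threshold(weak), "more markers")
})

test_that("pure-threshold selection floors the parental minimum", {
  q <- c(0.9953, 0.9981, 1.0, 0.41)
  labels <- c("RW", "PW", "PW", "F1")
  expect_equal(select_pure_threshold(q, labels), 0.995)
  expect_equal(select_pure_threshold(c(1, 1), c("PW", "PW")), 1)
  expect_error(select_pure_threshold(0.9, "F1"), "no wild parental")
  # a mislabelled F1 in the parental set surfaces via the pair invariant
  bad <- select_pure_threshold(c(0.5, 0.99), c("PW", "PW"))
  expect_error(threshold_pair(0.955, bad), "invalid thresholds")
})

test_that("threshold pair enforces ordering", {
  tp <- threshold_pair(0.955, 0.995)
  expect_s3_class(tp, "threshold_pair")
  expect_error(threshold_pair(0.995, 0.955), "invalid")
  expect_error(threshold_pair(0.4, 0.995), "invalid")
  expect_error(threshold_pair(0.955, 1.01), "invalid")
})

test_that("classification honours the exact boundary conventions", {
  tp <- threshold_pair(0.955, 0.995)
  cl <- classify_individuals(c(0.996, 0.995, 0.9949, 0.970, 0.955, 0.9549, 0.40),
                             tp)
  expect_equal(as.character(cl$assignment_class),
               c("pure", "pure", "older admixed", "older admixed",
                 "older admixed", "recent admixed", "recent admixed"))
  expect_equal(as.character(cl$management_category),
               c("operational pure", "operational pure", "introgressed",
                 "introgressed", "introgressed", "operational hybrid",
                 "operational hybrid"))
  # partition: exactly one category each; monotone in q
  expect_false(anyNA(cl$management_category))
  q <- sort(stats::runif(200))
  ranks <- as.integer(classify_individuals(q, tp)$management_category)
  expect_true(all(diff(ranks) >= 0))
})

test_that("error rates count type I and type II per definition", {
  tp <- threshold_pair(0.955, 0.995)
  df <- data.frame(
    individual_id = sprintf("i%d", 1:6),
    label = c("PW", "PW", "F1", "F1", "BC4W", "BC4W"),
    stringsAsFactors = FALSE
  )
  cl <- cbind(df, classify_individuals(c(0.999, 0.998, 0.3, 0.4, 0.997, 0.96),
                                       tp)[-1])
  cl$q_wild <- c(0.999, 0.998, 0.3, 0.4, 0.997, 0.96)
  er <- error_rates(cl)
  expect_equal(er$type_I, 0)            # all PW above t_pure
  expect_equal(er$type_II, 0.25)        # 1 of 4 admixed called pure
  expect_equal(unname(er$confusion["F1", "operational hybrid"]), 100)
  expect_gt(er$confusion["BC4W", "operational pure"], 0)
})
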