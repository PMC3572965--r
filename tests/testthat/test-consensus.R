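test_that("modal thresholds follow the round-then-mode rule", {
  expect_equal(modal_threshold(c(1.587, 1.587, 1.6, 2.1)), 1.587)
  # rounding to 3 decimals merges near-identical fold thresholds
  expect_equal(modal_threshold(c(1.58700001, 1.58699999, 2.5)), 1.587)
  # multimodal: the median of the modal set
  expect_equal(modal_threshold(c(1, 1, 3, 3, 9, 9)), 3)
  expect_equal(modal_threshold(c(1, 1, 5, 5)), 3)
  expect_equal(modal_threshold(4.2), 4.2)
})

test_that("the aggregation rule demands a strict fold majority", {
  folds <- data.frame(
    fold = 1:10,
    root_feature = c(rep("total_wml", 9), "frontal_wmlr"),
    root_threshold = c(rep(1.6, 6), rep(1.9, 3), 40),
    second_feature = c(rep("temporal_wmlr", 7), "parietal_wmlr",
                       "parietal_wmlr", NA),
    second_threshold = c(rep(0.7, 4), rep(0.9, 3), 30, 31, NA),
    stringsAsFactors = FALSE)
  cons <- wmlpatterns:::.consensus_from_folds(folds, 10L)
  expect_true(cons$stable)
  expect_identical(cons$root$feature, "total_wml")
  expect_equal(cons$root$threshold, 1.6)  # modal value among the nine
  expect_identical(cons$second$feature, "temporal_wmlr")
  expect_equal(cons$second$threshold, 0.7)
  # 5/5 at the root is not a strict majority
  split5 <- folds
  split5$root_feature <- rep(c("total_wml", "temporal_wmlr"), each = 5)
  out <- wmlpatterns:::.consensus_from_folds(split5, 10L)
  expect_false(out$stable)
  expect_match(out$reason, "root")
  # majority root but scattered second level: explicit instability
  scatter <- folds
  scatter$second_feature <- c("temporal_wmlr", "parietal_wmlr",
                              "frontal_wmlr", "occipital_wmlr", "total_wml",
                              "temporal_wmlr", "parietal_wmlr",
                              "frontal_wmlr", "occipital_wmlr", NA)
  out2 <- wmlpatterns:::.consensus_from_folds(scatter, 10L)
  expect_false(out2$stable)
  expect_match(out2$reason, "second")
})

test_that("identical fold trees give back the common tree", {
  set.seed(20)
  n <- 80
  total <- c(runif(n / 2, 0.1, 1), runif(n / 2, 3, 9))
  tempr <- c(runif(n * 0.3, 0, 0.4), runif(n * 0.7, 1.5, 6))[sample(n)]
  y <- total >= 2 & tempr >= 1  # fully separable planted structure
  f <- data.frame(total_wml = total, frontal_wmlr = runif(n, 40, 90),
                  parietal_wmlr = runif(n, 5, 50), temporal_wmlr = tempr,
                  occipital_wmlr = runif(n, 0, 5))
  cons <- consensus_tree(f, y, k = 10, min_leaf = 6, seed = 1)
  expect_true(cons$stable)
  expect_identical(cons$root$feature, "total_wml")
  expect_identical(cons$second$feature, "temporal_wmlr")
  expect_identical(unique(cons$fold_summaries$root_feature), "total_wml")
  # with a clean separation every fold finds the same cut region
  expect_lt(diff(range(cons$fold_summaries$root_threshold)), 1.5)
})

test_that("folds are stratified by outcome", {
  set.seed(21)
  y <- runif(120) < 0.25
  f <- data.frame(total_wml = rlnorm(120), frontal_wmlr = runif(120, 40, 90),
                  parietal_wmlr = runif(120, 5, 50),
                  temporal_wmlr = rlnorm(120, 0, 1),
                  occipital_wmlr = runif(120, 0, 5))
  set.seed(99)
  fold <- wmlpatterns:::.stratified_folds(y, 10L)
  per_fold <- table(fold, y)
  expect_true(max(per_fold[, "TRUE"]) - min(per_fold[, "TRUE"]) <= 1)
  expect_true(max(per_fold[, "FALSE"]) - min(per_fold[, "FALSE"]) <= 1)
})

test_that("patterns follow the two-threshold rule with >= boundaries", {
  cons <- fixed_consensus(root_threshold = 1.587, second_threshold = 0.65)
  f <- data.frame(
    total_wml = c(0.45, 5.4, 5.9, 1.587, 1.5869999),
    frontal_wmlr = 60, parietal_wmlr = 30,
    temporal_wmlr = c(2, 0.3, 1.9, 0.65, 3),
    occipital_wmlr = 2)
  pat <- assign_pattern(f, cons)
  expect_identical(as.character(pat),
                   c("pattern1",   # low total, whatever the shares
                     "pattern2",   # heavy load, spared temporal region
                     "pattern3",   # heavy load with temporal involvement
                     "pattern3",   # exactly at both thresholds: >= goes up
                     "pattern1"))  # just below the root threshold
  unstable <- consensus_tree(
    data.frame(total_wml = rep(c(1, 2), 30), frontal_wmlr = 60,
               parietal_wmlr = 30, temporal_wmlr = 5, occipital_wmlr = 5),
    rep(c(TRUE, FALSE), 30), k = 10, min_leaf = 6, seed = 2)
  if (!unstable$stable) expect_error(assign_pattern(f, unstable), "unstable")
})

test_that("consensus demands enough subjects per fold", {
  inst <- random_instance(30, 7)
  expect_error(consensus_tree(inst$features, inst$labels, k = 10,
                              min_leaf = 6), "k \\* min_leaf")
})
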