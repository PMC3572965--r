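test_that("gini impurity matches its closed form and bounds", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  # event/non-event margins of the emulated cohort (111 of 426)
  expect_equal(gini_impurity(c(111, 315)), 0.3853401, tolerance = 1e-6)
  expect_error(gini_impurity(c(0, 0)), "positive")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    g <- gini_impurity(rpois(k, 5) + c(1, rep(0, k - 1)))
    expect_gte(g, 0)
    expect_lt(g, 1)
  }
})

test_that("candidate thresholds are midpoints of distinct neighbours", {
  expect_equal(candidate_thresholds(c(1, 2, 3)), c(1.5, 2.5))
  expect_equal(candidate_thresholds(c(1, 1, 2)), 1.5)
  expect_length(candidate_thresholds(c(2, 2, 2)), 0)
  expect_error(candidate_thresholds(3), "two values")
  set.seed(2)
  v <- round(runif(20, 0, 5), 2)
  expect_length(candidate_thresholds(v), length(unique(v)) - 1L)
})

test_that("the midpoint candidate set is as good as a dense grid", {
  set.seed(3)
  v <- rlnorm(20, 0, 1)
  y <- runif(20) < plogis(v - 1)
  if (length(unique(y)) < 2) y[1:3] <- !y[1:3]
  f <- data.frame(total_wml = v, frontal_wmlr = 0, parietal_wmlr = 0,
                  temporal_wmlr = 0, occipital_wmlr = 0)
  got <- best_split(f, y)
  grid <- seq(min(v) + 1e-9, max(v) - 1e-9, length.out = 10000)
  wg_at <- function(thr) {
    left <- v < thr
    if (!any(left) || all(left)) return(Inf)
    (sum(left) * oracle_gini(y[left]) +
       sum(!left) * oracle_gini(y[!left])) / length(y)
  }
  expect_equal(got$impurity, min(vapply(grid, wg_at, numeric(1))),
               tolerance = 1e-12)
})

test_that("best_split equals brute-force enumeration on small instances", {
  for (seed in 1:40) {
    inst <- random_instance(sample(4:25, 1), seed)
    ml <- sample(1:3, 1)
    got <- best_split(inst$features, inst$labels, min_leaf = ml)
    want <- oracle_best_split(inst$features, inst$labels, min_leaf = ml)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$impurity, want$impurity, tolerance = 1e-12)
    }
  }
})

test_that("perfectly separable data splits cleanly between the classes", {
  f <- data.frame(total_wml = c(1, 2, 3, 10, 11, 12), frontal_wmlr = 50,
                  parietal_wmlr = 30, temporal_wmlr = 2, occipital_wmlr = 1)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  s <- best_split(f, y)
  expect_identical(s$feature, "total_wml")
  expect_equal(s$threshold, 6.5)
  expect_equal(s$impurity, 0)
  # shuffling the labels can never beat the separable impurity
  set.seed(4)
  for (i in 1:100) {
    sh <- best_split(f, sample(y))
    if (!is.null(sh)) expect_gte(sh$impurity, s$impurity)
  }
})

test_that("growth stops at pure nodes and the min-leaf rule", {
  f <- data.frame(total_wml = 1:6, frontal_wmlr = 6:1, parietal_wmlr = 0,
                  temporal_wmlr = c(0, 1, 0, 1, 0, 1), occipital_wmlr = 0)
  y <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  tr <- build_tree(f, y, min_leaf = 6)
  expect_identical(tr$node, "leaf")  # any split would starve a child
  pure <- build_tree(f, rep(FALSE, 6), min_leaf = 2)
  expect_identical(pure$node, "leaf")
  expect_error(build_tree(f[1:3, ], y[1:3], min_leaf = 6), "min_leaf")
})

test_that("a planted two-threshold structure is recovered at depth 2", {
  set.seed(6)
  n <- 60
  total <- c(runif(30, 0.2, 1.5), runif(30, 2.5, 8))
  tempr <- c(runif(27, 0, 0.8), runif(33, 1.2, 6))[sample(n)]
  y <- total >= 2 & tempr >= 1
  f <- data.frame(total_wml = total, frontal_wmlr = runif(n, 40, 90),
                  parietal_wmlr = runif(n, 5, 50), temporal_wmlr = tempr,
                  occipital_wmlr = runif(n, 0, 5))
  tr <- build_tree(f, y, min_leaf = 6)
  expect_identical(tr$node, "split")
  expect_identical(tr$feature, "total_wml")
  expect_gt(tr$threshold, 1.5)
  expect_lt(tr$threshold, 2.5)
  expect_identical(tr$right$feature, "temporal_wmlr")
  # the cut falls in the planted gap: between the largest low-share and
  # the smallest high-share value present in the heavy-load node
  expect_gt(tr$right$threshold, 0.6)
  expect_lt(tr$right$threshold, 3.6)
  expect_identical(tr$left$node, "leaf")
})

test_that("full trees equal an independently coded recursive oracle", {
  for (seed in 101:115) {
    inst <- random_instance(sample(10:25, 1), seed)
    ml <- sample(2:4, 1)
    got <- build_tree(inst$features, inst$labels, min_leaf = ml)
    want <- oracle_tree(inst$features, inst$labels, min_leaf = ml)
    expect_same_tree(got, want)
  }
})

test_that("accepted splits never increase impurity and avoid data values", {
  walk <- function(node, features_all) {
    if (node$node == "leaf") return(invisible(NULL))
    parent <- gini_impurity(node$counts)
    expect_lte(node$impurity, parent + 1e-12)
    expect_false(node$threshold %in% features_all[[node$feature]])
    walk(node$left, features_all)
    walk(node$right, features_all)
  }
  for (seed in 201:208) {
    inst <- random_instance(25, seed)
    tr <- build_tree(inst$features, inst$labels, min_leaf = 3)
    walk(tr, inst$features)
  }
})

test_that("the tree does not depend on subject order", {
  inst <- random_instance(25, 301)
  tr1 <- build_tree(inst$features, inst$labels, min_leaf = 3)
  set.seed(302)
  perm <- sample(25)
  tr2 <- build_tree(inst$features[perm, ], inst$labels[perm], min_leaf = 3)
  expect_equal(unclass(tr1)[c("feature", "threshold", "n", "counts")],
               unclass(tr2)[c("feature", "threshold", "n", "counts")])
  expect_same_tree(tr2, oracle_tree(inst$features, inst$labels, 3L))
})
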