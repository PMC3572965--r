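# Independent oracles, coded separately from the implementation paths
# they check: a quadratic-time exhaustive Gini scan, a recursive tree
# grower built on it, and a Newton maximiser of the left-truncated Cox
# partial likelihood.

FEATS <- c("total_wml", "frontal_wmlr", "parietal_wmlr", "temporal_wmlr",
           "occipital_wmlr")

oracle_gini <- function(y) {
  p <- mean(y)
  1 - p^2 - (1 - p)^2
}

# double loop over every (feature, midpoint threshold) pair; same
# deterministic tie rule as the contract: feature priority order, then
# the smaller threshold, strict 1e-12 improvement
oracle_best_split <- function(features, labels, min_leaf = 1L) {
  y <- as.logical(labels)
  n <- length(y)
  if (n < 2L || length(unique(y)) < 2L) return(NULL)
  best <- NULL
  for (f in FEATS) {
    v <- features[[f]]
    sv <- sort(unique(v))
    if (length(sv) < 2L) next
    for (thr in (sv[-1L] + sv[-length(sv)]) / 2) {
      left <- v < thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      wg <- (sum(left) * oracle_gini(y[left]) +
               sum(!left) * oracle_gini(y[!left])) / n
      if (is.null(best) || wg < best$impurity - 1e-12) {
        best <- list(feature = f, threshold = thr, impurity = wg)
      }
    }
  }
  best
}

oracle_tree <- function(features, labels, min_leaf = 6L) {
  y <- as.logical(labels)
  split <- oracle_best_split(features, y, min_leaf = min_leaf)
  if (is.null(split)) {
    return(list(leaf = TRUE, n = length(y), events = sum(y)))
  }
  left <- features[[split$feature]] < split$threshold
  list(leaf = FALSE, feature = split$feature, threshold = split$threshold,
       n = length(y), events = sum(y),
       left = oracle_tree(features[left, , drop = FALSE], y[left], min_leaf),
       right = oracle_tree(features[!left, , drop = FALSE], y[!left],
                           min_leaf))
}

# compare a fitted wml_tree against the oracle's nested-list tree
expect_same_tree <- function(node, oracle) {
  expect_equal(node$n, oracle$n)
  expect_equal(unname(node$counts[["event"]]), oracle$events)
  if (oracle$leaf) {
    expect_identical(node$node, "leaf")
  } else {
    expect_identical(node$node, "split")
    expect_identical(node$feature, oracle$feature)
    expect_equal(node$threshold, oracle$threshold)
    expect_same_tree(node$left, oracle$left)
    expect_same_tree(node$right, oracle$right)
  }
}

# random small feature/label instance with deliberate duplicated values
random_instance <- function(n, seed) {
  set.seed(seed)
  f <- data.frame(
    total_wml = round(rlnorm(n, 0, 1), sample(0:2, 1)),
    frontal_wmlr = round(runif(n, 0, 100), 1),
    parietal_wmlr = round(runif(n, 0, 60), sample(0:1, 1)),
    temporal_wmlr = sample(c(0, round(rlnorm(n, 1, 1), 2)), n, replace = TRUE),
    occipital_wmlr = round(runif(n, 0, 10), 1))
  list(features = f, labels = runif(n) < 0.35)
}

# Newton-Raphson on the left-truncated Cox partial likelihood (untied
# event times; risk set at event age t is entry < t <= exit)
oracle_cox_coef <- function(entry, exit, event, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    U <- rep(0, p)
    info <- matrix(0, p, p)
    for (i in which(event)) {
      at_risk <- entry < exit[i] & exit >= exit[i]
      w <- exp(eta[at_risk])
      Xr <- X[at_risk, , drop = FALSE]
      s0 <- sum(w)
      s1 <- colSums(Xr * w)
      s2 <- crossprod(Xr, Xr * w)
      U <- U + X[i, ] - s1 / s0
      info <- info + s2 / s0 - tcrossprod(s1 / s0)
    }
    step <- solve(info, U)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# random left-truncated survival data without event-time ties
random_cox_data <- function(n, seed, p = 2L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p, 0, 0.5)
  entry <- 65 + runif(n, 0, 10)
  gap <- rexp(n, 0.2 * exp(drop(X %*% beta)))
  cens <- runif(n, 1, 8)
  exit <- entry + pmin(gap, cens)
  event <- gap <= cens
  if (sum(event) < 3L) return(random_cox_data(n, seed + 1000L, p))
  data.frame(entry_age = entry, exit_age = exit, event = event,
             zero_exposure = FALSE, X)
}
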