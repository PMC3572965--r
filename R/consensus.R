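# Cross-validation consensus over fold trees, and pattern assignment.
#
# Ten trees are grown by 10-fold cross-validation (each on nine tenths of
# the subjects, folds stratified by outcome). The consensus retains, at
# the root and again at the second level inside the root's ">=" branch,
# the descriptor used by a strict majority of the fold trees, with its
# threshold set to the modal value among those trees. The consensus is
# truncated at depth 2: the final tree has exactly two splits, defining
# patterns 1 (below the root threshold), 2 (at or above the root
# threshold, below the second threshold) and 3 (at or above both).

#' Modal threshold of a set of fold thresholds
#'
#' Thresholds are continuous, so the mode is taken after rounding to
#' `digits` decimals (default 3, i.e. 0.001 ml or 0.001 percentage
#' points); if several rounded values are equally frequent the median of
#' the modal set is returned.
#'
#' @param x numeric thresholds from the fold trees.
#' @param digits rounding applied before the mode.
#' @return A single numeric threshold.
#' @export
modal_threshold <- function(x, digits = 3L) {
  stopifnot(length(x) > 0L, all(is.finite(x)))
  r <- round(x, digits)
  tb <- table(r)
  modal <- as.numeric(names(tb)[tb == max(tb)])
  if (length(modal) == 1L) modal else stats::median(modal)
}

# stratified-by-label fold assignment, deterministic given the RNG state
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Consensus tree from k-fold cross-validation
#'
#' Grows one Gini tree per fold (each on the other `k - 1` folds; folds
#' are a seeded random partition stratified by outcome) and aggregates:
#' the consensus root descriptor is the one used at the root by a strict
#' majority (> k/2) of the fold trees, with threshold the modal value
#' (see [modal_threshold()]) among those trees; the consensus second
#' split is derived the same way from the split at the right (">=")
#' child of the root, among the fold trees whose root agrees with the
#' consensus root. If either position has no strict-majority descriptor
#' the result is explicitly flagged unstable rather than silently
#' picking one.
#'
#' @inheritParams build_tree
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold partition.
#' @return An object of class `consensus_tree`: list with `root` and
#'   `second` (each `NULL` or `list(feature, threshold)`), `stable`
#'   (TRUE when both consensus splits exist), `reason` (diagnostic when
#'   unstable), `fold_summaries` (one row per fold: root and
#'   second-level feature/threshold), `fold_trees`, `k`, `min_leaf`,
#'   `seed`.
#' @export
consensus_tree <- function(features, labels, k = 10L, min_leaf = 6L,
                           seed = NULL) {
  features <- .check_features(features)
  y <- .as_event(labels)
  n <- length(y)
  if (n < k * min_leaf) {
    stop("need at least k * min_leaf subjects", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fold <- .stratified_folds(y, k)
  fold_trees <- lapply(seq_len(k), function(f) {
    train <- fold != f
    build_tree(features[train, , drop = FALSE], y[train], min_leaf = min_leaf)
  })
  summ <- do.call(rbind, lapply(seq_len(k), function(f) {
    tr <- fold_trees[[f]]
    root <- node_split(tr)
    second <- if (!is.null(root)) node_split(tr$right) else NULL
    data.frame(fold = f,
               root_feature = if (is.null(root)) NA_character_ else root$feature,
               root_threshold = if (is.null(root)) NA_real_ else root$threshold,
               second_feature = if (is.null(second)) NA_character_ else second$feature,
               second_threshold = if (is.null(second)) NA_real_ else second$threshold,
               stringsAsFactors = FALSE)
  }))
  cons <- .consensus_from_folds(summ, k)
  structure(c(cons,
              list(fold_summaries = summ, fold_trees = fold_trees, k = k,
                   min_leaf = min_leaf, seed = seed)),
            class = "consensus_tree")
}

# aggregation rule, separated for direct testing
.consensus_from_folds <- function(summ, k) {
  maj <- function(feats, total) {
    feats <- feats[!is.na(feats)]
    if (length(feats) == 0L) return(NULL)
    tb <- sort(table(feats), decreasing = TRUE)
    if (tb[1L] <= total / 2) return(NULL)  # no strict majority
    names(tb)[1L]
  }
  root_f <- maj(summ$root_feature, k)
  if (is.null(root_f)) {
    return(list(root = NULL, second = NULL, stable = FALSE,
                reason = "no strict-majority root descriptor across folds"))
  }
  root <- list(feature = root_f,
               threshold = modal_threshold(
                 summ$root_threshold[!is.na(summ$root_feature) &
                                       summ$root_feature == root_f]))
  sub <- summ[!is.na(summ$root_feature) & summ$root_feature == root_f, ,
              drop = FALSE]
  sec_f <- maj(sub$second_feature, nrow(sub))
  if (is.null(sec_f)) {
    return(list(root = root, second = NULL, stable = FALSE,
                reason = "no strict-majority second-level descriptor"))
  }
  second <- list(feature = sec_f,
                 threshold = modal_threshold(
                   sub$second_threshold[!is.na(sub$second_feature) &
                                          sub$second_feature == sec_f]))
  list(root = root, second = second, stable = TRUE, reason = NA_character_)
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("<consensus_tree>", x$k, "fold trees, min_leaf =", x$min_leaf, "\n")
  if (!is.null(x$root)) {
    cat(sprintf("  root:   %s < %.4g (pattern 1) vs >= (patterns 2/3)\n",
                x$root$feature, x$root$threshold))
  }
  if (!is.null(x$second)) {
    cat(sprintf("  second: %s < %.4g (pattern 2) vs >= (pattern 3)\n",
                x$second$feature, x$second$threshold))
  }
  if (!isTRUE(x$stable)) cat("  UNSTABLE:", x$reason, "\n")
  invisible(x)
}

#' Manually specified depth-2 consensus
#'
#' Builds a `consensus_tree` directly from a root and second
#' (feature, threshold) pair, bypassing cross-validation — used to apply
#' externally fixed thresholds (for example the generator's planted
#' truth) with the same assignment code path.
#'
#' @param root_feature,root_threshold root split (pattern 1 below).
#' @param second_feature,second_threshold second split within the root's
#'   `>=` branch (pattern 2 below, pattern 3 at or above).
#' @return A stable `consensus_tree` with no fold trees.
#' @export
fixed_consensus <- function(root_feature = "total_wml",
                            root_threshold = 1.587,
                            second_feature = "temporal_wmlr",
                            second_threshold = 0.65) {
  structure(list(root = list(feature = root_feature,
                             threshold = root_threshold),
                 second = list(feature = second_feature,
                               threshold = second_threshold),
                 stable = TRUE, reason = NA_character_,
                 fold_summaries = NULL, fold_trees = NULL,
                 k = 0L, min_leaf = NA_integer_, seed = NULL),
            class = "consensus_tree")
}

#' Assign WML patterns from a consensus tree
#'
#' Pattern 1: root descriptor below the root threshold. Otherwise
#' pattern 2 when the second descriptor is below the second threshold,
#' else pattern 3. Boundary values go right: a subject exactly at a
#' threshold is on the `>=` side of that split.
#'
#' @param features data frame with the five descriptor columns (one row
#'   per subject).
#' @param consensus a stable [consensus_tree].
#' @return Factor with levels `pattern1`, `pattern2`, `pattern3`.
#' @export
assign_pattern <- function(features, consensus) {
  stopifnot(inherits(consensus, "consensus_tree"))
  if (!isTRUE(consensus$stable) || is.null(consensus$root) ||
      is.null(consensus$second)) {
    stop("cannot assign patterns from an unstable consensus (",
         consensus$reason, ")", call. = FALSE)
  }
  features <- .check_features(features)
  low_root <- features[[consensus$root$feature]] < consensus$root$threshold
  low_second <- features[[consensus$second$feature]] < consensus$second$threshold
  out <- ifelse(low_root, "pattern1", ifelse(low_second, "pattern2", "pattern3"))
  factor(out, levels = PATTERN_LEVELS)
}
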