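# Exhaustive Gini CART over the five WML descriptors.
#
# The tree asks binary questions "is descriptor x below threshold t?"
# (left branch: x < t, right branch: x >= t). At every node all five
# descriptors are scanned over every candidate threshold (the midpoints
# between successive distinct observed values) and the combination with
# the lowest weighted Gini impurity of the two children is retained.
# Growth stops when a node is pure or when any further split would leave
# a child with fewer than `min_leaf` observations (default 6).

# impurity comparisons use this tolerance; exact ties are resolved by the
# fixed descriptor priority (order of WML_FEATURE_NAMES), then by the
# smaller threshold
.GINI_EPS <- 1e-12

#' Gini impurity of a class-count vector
#'
#' `1 - sum(p_i^2)` with `p_i` the class proportions. Zero for a pure
#' node; `0.5` for an evenly mixed binary node.
#'
#' @param class_counts non-negative counts, at least one positive.
#' @return Impurity in `[0, 1)`.
#' @examples
#' gini_impurity(c(10, 0))  # 0
#' gini_impurity(c(5, 5))   # 0.5
#' @export
gini_impurity <- function(class_counts) {
  if (anyNA(class_counts) || any(class_counts < 0)) {
    stop("class counts must be non-negative", call. = FALSE)
  }
  n <- sum(class_counts)
  if (n == 0) stop("at least one class count must be positive", call. = FALSE)
  1 - sum((class_counts / n)^2)
}

#' Candidate split thresholds for a feature
#'
#' All midpoints between successive distinct sorted values — the complete
#' candidate set for an exhaustive split search, since any threshold
#' strictly between the same pair of observations induces the same
#' partition.
#'
#' @param values numeric vector with at least two elements.
#' @return Sorted numeric vector of length `(number of distinct values) - 1`
#'   (empty when all values are identical).
#' @examples
#' candidate_thresholds(c(1, 2, 3))  # 1.5 2.5
#' candidate_thresholds(c(1, 1, 2))  # 1.5
#' @export
candidate_thresholds <- function(values) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  v <- sort(unique(values))
  if (length(v) < 2L) return(numeric(0))
  (v[-1L] + v[-length(v)]) / 2
}

# labels -> logical event vector
.as_event <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels %in% c("event", "TRUE", "mci", "dementia"))
  as.logical(labels)
}

.check_features <- function(features) {
  miss <- setdiff(WML_FEATURE_NAMES, names(features))
  if (length(miss) > 0L) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  features
}

#' Best Gini split at a node
#'
#' Exhaustively scans every descriptor and every candidate threshold
#' (see [candidate_thresholds()]) and returns the pair minimising the
#' weighted child impurity
#' `n_L/n * gini(left) + n_R/n * gini(right)`.
#' Candidates that would leave either child with fewer than `min_leaf`
#' observations are excluded. Ties (within `1e-12`) are broken by the
#' fixed descriptor priority `total_wml`, `frontal_wmlr`,
#' `parietal_wmlr`, `temporal_wmlr`, `occipital_wmlr`, then by the
#' smaller threshold, so the result does not depend on subject order.
#'
#' @param features data frame containing the five descriptor columns.
#' @param labels per-subject outcome; `TRUE`/`"event"` marks incident
#'   MCI/dementia.
#' @param min_leaf minimum child size for an admissible split.
#' @return `NULL` when no admissible split exists (single-class node or no
#'   candidate threshold); otherwise a list with `feature`, `threshold`,
#'   `impurity` (the weighted child impurity), `decrease` (parent impurity
#'   minus `impurity`, always `>= 0`), `n_left` and `n_right`.
#' @export
best_split <- function(features, labels, min_leaf = 1L) {
  features <- .check_features(features)
  y <- .as_event(labels)
  n <- length(y)
  stopifnot(nrow(features) == n)
  n_event <- sum(y)
  if (n < 2L || n_event == 0L || n_event == n) return(NULL)
  parent <- gini_impurity(c(n - n_event, n_event))
  best <- NULL
  for (f in WML_FEATURE_NAMES) {
    v <- features[[f]]
    ord <- order(v, method = "radix")
    vs <- v[ord]
    es <- cumsum(y[ord])
    idx <- which(vs[-n] < vs[-1L])
    idx <- idx[idx >= min_leaf & (n - idx) >= min_leaf]
    if (length(idx) == 0L) next
    n_l <- idx
    e_l <- es[idx]
    h_l <- n_l - e_l
    n_r <- n - n_l
    e_r <- n_event - e_l
    h_r <- n_r - e_r
    g_l <- 1 - (e_l / n_l)^2 - (h_l / n_l)^2
    g_r <- 1 - (e_r / n_r)^2 - (h_r / n_r)^2
    wg <- (n_l * g_l + n_r * g_r) / n
    m <- min(wg)
    if (is.null(best) || m < best$impurity - .GINI_EPS) {
      j <- idx[which(wg <= m + .GINI_EPS)[1L]]  # smallest threshold among ties
      best <- list(feature = f,
                   threshold = (vs[j] + vs[j + 1L]) / 2,
                   impurity = m,
                   decrease = parent - m,
                   n_left = j,
                   n_right = n - j)
    }
  }
  best
}

#' Grow a Gini decision tree
#'
#' Recursive binary partition of the subjects by [best_split()]. A node
#' becomes a leaf when it is pure, or when no split can leave both
#' children with at least `min_leaf` observations (the stopping rule
#' "fewer than `min_leaf` observations in a leaf" never triggers because
#' such splits are never accepted). The tree is deterministic and
#' invariant to subject order.
#'
#' @inheritParams best_split
#' @param min_leaf minimum number of training observations per leaf
#'   (default 6).
#' @return The root `wml_tree_node` (class also `wml_tree`): internal
#'   nodes carry `feature`, `threshold` (left child: `feature <
#'   threshold`), `left`, `right`; every node carries `n`, `counts`
#'   (healthy, event) and the majority class.
#' @export
build_tree <- function(features, labels, min_leaf = 6L) {
  features <- .check_features(features)
  y <- .as_event(labels)
  if (length(y) < min_leaf) {
    stop("fewer subjects than min_leaf", call. = FALSE)
  }
  root <- .grow(features, y, min_leaf)
  class(root) <- c("wml_tree", class(root))
  attr(root, "min_leaf") <- min_leaf
  root
}

.node_counts <- function(y) c(healthy = sum(!y), event = sum(y))

.grow <- function(features, y, min_leaf) {
  counts <- .node_counts(y)
  base <- list(n = length(y), counts = counts,
               majority = names(counts)[which.max(counts)])
  split <- best_split(features, y, min_leaf = min_leaf)
  if (is.null(split)) {
    node <- c(list(node = "leaf"), base)
  } else {
    left <- features[[split$feature]] < split$threshold
    node <- c(list(node = "split", feature = split$feature,
                   threshold = split$threshold, impurity = split$impurity),
              base,
              list(left = .grow(features[left, , drop = FALSE], y[left], min_leaf),
                   right = .grow(features[!left, , drop = FALSE], y[!left], min_leaf)))
  }
  class(node) <- "wml_tree_node"
  node
}

#' @export
print.wml_tree <- function(x, ...) {
  cat("<wml_tree> Gini CART, min_leaf =", attr(x, "min_leaf"), "\n")
  .print_node(x, indent = 0L)
  invisible(x)
}

.print_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$node == "leaf") {
    cat(sprintf("%sleaf: n=%d (healthy %d, event %d) -> %s\n", pad, node$n,
                node$counts[["healthy"]], node$counts[["event"]],
                node$majority))
  } else {
    cat(sprintf("%s%s < %.4g ? (n=%d, healthy %d, event %d)\n", pad,
                node$feature, node$threshold, node$n,
                node$counts[["healthy"]], node$counts[["event"]]))
    .print_node(node$left, indent + 1L)
    .print_node(node$right, indent + 1L)
  }
}

# (feature, threshold) of a node's split, or NULL for a leaf
node_split <- function(node) {
  if (is.null(node) || node$node == "leaf") return(NULL)
  list(feature = node$feature, threshold = node$threshold)
}

tree_depth <- function(node) {
  if (node$node == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

# every leaf of the fitted tree, as a data frame of counts
tree_leaves <- function(node) {
  if (node$node == "leaf") {
    return(data.frame(n = node$n, healthy = node$counts[["healthy"]],
                      event = node$counts[["event"]]))
  }
  rbind(tree_leaves(node$left), tree_leaves(node$right))
}
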