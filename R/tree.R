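#' Decision-tree induction parameters
#'
#' @param min_leaf_fraction Minimum leaf size as a fraction of the
#'   training-set size; converted to an absolute count by ceiling, so 1%
#'   of 16 instances still means at least 1.
#' @param confidence_factor Confidence level of the pessimistic pruning
#'   error estimate (smaller prunes harder).
#' @param pruning Whether to apply pessimistic subtree-replacement
#'   pruning after growth.
#' @return An object of class `tree_params`.
#' @export
tree_params <- function(min_leaf_fraction = 0.01, confidence_factor = 0.25,
                        pruning = TRUE) {
  if (!(min_leaf_fraction > 0 && min_leaf_fraction < 1))
    stop("min_leaf_fraction must be in (0, 1)")
  if (!(confidence_factor > 0 && confidence_factor < 0.5))
    stop("confidence_factor must be in (0, 0.5)")
  structure(list(min_leaf_fraction = min_leaf_fraction,
                 confidence_factor = confidence_factor,
                 pruning = isTRUE(pruning)),
            class = "tree_params")
}

#' Shannon entropy of a class-count vector
#'
#' @param class_counts Non-negative counts, sum > 0.
#' @return Entropy in bits: -sum p_i log2 p_i over nonzero classes.
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("negative class counts")
  n <- sum(class_counts)
  if (n == 0) stop("all-zero class counts")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

#' Gain ratio of a binary partition
#'
#' Information gain of splitting `parent_counts` into `left_counts` and
#' `right_counts`, divided by the split information (the entropy of the
#' left/right sizes). Penalizes fragmentary partitions. Defined as 0 when
#' the split information is 0 (one side empty).
#'
#' @param parent_counts,left_counts,right_counts Class-count vectors;
#'   left + right must equal parent elementwise.
#' @return The gain ratio (0 to 1).
#' @export
gain_ratio <- function(parent_counts, left_counts, right_counts) {
  if (!isTRUE(all.equal(unname(left_counts + right_counts),
                        unname(parent_counts))))
    stop("left and right counts do not partition the parent counts")
  n <- sum(parent_counts)
  nl <- sum(left_counts)
  nr <- sum(right_counts)
  if (nl == 0 || nr == 0) return(0)
  gain <- entropy(parent_counts) -
    (nl / n) * entropy(left_counts) - (nr / n) * entropy(right_counts)
  split_info <- entropy(c(nl, nr))
  if (split_info == 0) return(0)
  gain / split_info
}

# Fast path used during induction: candidate thresholds at midpoints
# between consecutive distinct sorted values; among splits with positive
# gain and >= min_leaf instances on both sides, pick max gain ratio,
# breaking ties toward the lowest threshold.
.best_split_vec <- function(values, class_idx, n_classes, min_leaf) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(NULL)
  parent <- tabulate(class_idx, n_classes)
  h_parent <- entropy(parent)
  n <- length(values)
  best <- NULL
  for (i in seq_len(length(u) - 1L)) {
    thr <- (u[i] + u[i + 1L]) / 2
    left_mask <- values <= thr
    nl <- sum(left_mask)
    nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    left <- tabulate(class_idx[left_mask], n_classes)
    right <- parent - left
    gain <- h_parent - (nl / n) * entropy(left) - (nr / n) * entropy(right)
    if (gain <= 1e-12) next
    ratio <- gain / entropy(c(nl, nr))
    if (is.null(best) || ratio > best$gain_ratio + 1e-9) {
      best <- list(threshold = thr, gain_ratio = ratio, gain = gain)
    }
  }
  best
}

#' Best threshold split of one numeric attribute
#'
#' Evaluates every candidate threshold (midpoints between consecutive
#' distinct sorted values of the attribute) and returns the one with the
#' highest gain ratio among splits that leave at least `min_leaf_count`
#' instances on each side and have strictly positive information gain.
#'
#' @param table Feature table data frame (with a `Class` column).
#' @param attribute Name of a numeric column to split on.
#' @param min_leaf_count Minimum instances per side.
#' @return A list with `threshold`, `gain_ratio`, `gain`, or `NULL` if no
#'   admissible split exists.
#' @export
best_split <- function(table, attribute, min_leaf_count = 1L) {
  if (!attribute %in% names(table))
    stop("unknown attribute: '", attribute, "'")
  cls <- factor(table$Class)
  .best_split_vec(table[[attribute]], as.integer(cls), nlevels(cls),
                  min_leaf_count)
}

.make_leaf <- function(counts) {
  list(leaf = TRUE, counts = counts,
       prediction = names(counts)[which.max(counts)],
       n = sum(counts))
}

# Upper confidence bound on the true error rate of a leaf observed to
# make e errors out of n, at confidence level cf (Wilson score interval).
.pessimistic_error_rate <- function(e, n, cf) {
  z <- qnorm(1 - cf)
  f <- e / n
  (f + z^2 / (2 * n) + z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

.node_est_errors <- function(counts, cf) {
  n <- sum(counts)
  e <- n - max(counts)
  n * .pessimistic_error_rate(e, n, cf)
}

# Bottom-up subtree replacement: a subtree collapses to a leaf when the
# leaf's pessimistic error estimate does not exceed the sum of its
# descendant leaves' estimates.
.prune_node <- function(node, cf) {
  if (node$leaf) return(node)
  node$left <- .prune_node(node$left, cf)
  node$right <- .prune_node(node$right, cf)
  subtree_err <- .subtree_est_errors(node, cf)
  leaf_err <- .node_est_errors(node$counts, cf)
  if (leaf_err <= subtree_err + 1e-9) return(.make_leaf(node$counts))
  node
}

.subtree_est_errors <- function(node, cf) {
  if (node$leaf) return(.node_est_errors(node$counts, cf))
  .subtree_est_errors(node$left, cf) + .subtree_est_errors(node$right, cf)
}

#' Induce a C4.5-style decision tree
#'
#' Recursive binary induction on numeric attributes: at each node the
#' attribute/threshold pair with the highest gain ratio (among splits with
#' positive information gain and at least the minimum leaf count on both
#' sides) is chosen; growth stops at class purity, when no admissible
#' split exists, or when fewer than twice the minimum leaf count remain.
#' Ties on gain ratio are broken toward the earlier attribute column, then
#' the lower threshold, so induction is deterministic given the table.
#' Pessimistic subtree-replacement pruning follows when enabled.
#'
#' All non-`Class` columns (including `Time`) are candidate attributes.
#'
#' @param table Feature table data frame.
#' @param params A [tree_params()].
#' @return An object of class `eeg_tree`.
#' @export
induce_tree <- function(table, params = tree_params()) {
  check_feature_table(table)
  attributes <- setdiff(names(table), "Class")
  cls <- factor(table$Class)
  n_classes <- nlevels(cls)
  class_levels <- levels(cls)
  n <- nrow(table)
  min_leaf <- max(1L, as.integer(ceiling(params$min_leaf_fraction * n)))
  X <- lapply(attributes, function(a) table[[a]])
  names(X) <- attributes
  ci <- as.integer(cls)

  grow <- function(rows) {
    counts <- tabulate(ci[rows], n_classes)
    names(counts) <- class_levels
    if (sum(counts > 0) <= 1L || length(rows) < 2L * min_leaf)
      return(.make_leaf(counts))
    best <- NULL
    for (a in attributes) {
      s <- .best_split_vec(X[[a]][rows], ci[rows], n_classes, min_leaf)
      if (!is.null(s) &&
          (is.null(best) || s$gain_ratio > best$gain_ratio + 1e-9)) {
        best <- c(s, list(attribute = a))
      }
    }
    if (is.null(best)) return(.make_leaf(counts))
    left_rows <- rows[X[[best$attribute]][rows] <= best$threshold]
    right_rows <- setdiff(rows, left_rows)
    list(leaf = FALSE, attribute = best$attribute,
         threshold = best$threshold, counts = counts,
         prediction = names(counts)[which.max(counts)],
         n = length(rows),
         left = grow(left_rows), right = grow(right_rows))
  }

  root <- grow(seq_len(n))
  if (params$pruning) root <- .prune_node(root, params$confidence_factor)

  structure(list(root = root, attributes = attributes,
                 classes = class_levels, params = params,
                 n_train = n, min_leaf_count = min_leaf),
            class = "eeg_tree")
}

#' Predict classes with an induced tree
#'
#' Follows each instance down the tree: `attribute <= threshold` goes
#' left, `> threshold` goes right; the leaf's majority class is returned.
#'
#' @param object An `eeg_tree`.
#' @param newdata Data frame containing every attribute the tree tests.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.eeg_tree <- function(object, newdata, ...) {
  tested <- tree_split_attributes(object)
  missing <- setdiff(names(tested), names(newdata))
  if (length(missing))
    stop("instance is missing tested attribute(s): ",
         paste(missing, collapse = ", "))
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object$root
    while (!node$leaf) {
      v <- newdata[[node$attribute]][i]
      node <- if (v <= node$threshold) node$left else node$right
    }
    node$prediction
  }, character(1))
}

#' Split-attribute usage counts of a tree
#'
#' @param model An `eeg_tree`.
#' @return Named integer vector: attribute name -> number of internal
#'   nodes testing it (empty for a single-leaf tree).
#' @export
tree_split_attributes <- function(model) {
  counts <- integer(0)
  walk <- function(node) {
    if (node$leaf) return(invisible())
    counts[node$attribute] <<- (counts[node$attribute] %||% 0L) + 1L
    walk(node$left)
    walk(node$right)
  }
  walk(model$root)
  counts
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Number of leaves of a tree
#' @param model An `eeg_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(model) {
  walk <- function(node) if (node$leaf) 1L else walk(node$left) + walk(node$right)
  walk(model$root)
}

#' Total node count of a tree
#' @param model An `eeg_tree`.
#' @return Integer node count (internal + leaves).
#' @export
n_nodes <- function(model) {
  walk <- function(node) if (node$leaf) 1L else 1L + walk(node$left) + walk(node$right)
  walk(model$root)
}

#' @export
print.eeg_tree <- function(x, ...) {
  cat(sprintf("<eeg_tree> %d instances, %d leaves\n", x$n_train, n_leaves(x)))
  cat(render_indented(x), sep = "\n")
  invisible(x)
}
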