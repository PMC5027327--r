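#' Construct a decision tree by hand
#'
#' Builders for assembling an `eeg_tree` directly, useful for encoding a
#' published tree structure (for rule extraction or attribution) without
#' re-inducing it from data.
#'
#' @param class Leaf class label.
#' @param n Training support of the leaf.
#' @return `tree_leaf` / `tree_split`: a tree node; `manual_tree`: an
#'   `eeg_tree`.
#' @examples
#' t <- manual_tree(tree_split("Time", 14,
#'        tree_leaf("cube", 4),
#'        tree_leaf("ball", 12)))
#' extract_rules(t)
#' @export
tree_leaf <- function(class, n = 0L) {
  counts <- structure(as.integer(n), names = class)
  list(leaf = TRUE, counts = counts, prediction = class, n = as.integer(n))
}

#' @rdname tree_leaf
#' @param attribute Attribute name tested at the node.
#' @param threshold Numeric split threshold (`<=` left, `>` right).
#' @param left,right Child nodes.
#' @export
tree_split <- function(attribute, threshold, left, right) {
  counts <- .merge_counts(left$counts, right$counts)
  list(leaf = FALSE, attribute = attribute, threshold = threshold,
       counts = counts, prediction = names(counts)[which.max(counts)],
       n = sum(counts), left = left, right = right)
}

.merge_counts <- function(a, b) {
  classes <- union(names(a), names(b))
  out <- structure(integer(length(classes)), names = classes)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' @rdname tree_leaf
#' @param root Root node built from [tree_split()] / [tree_leaf()].
#' @param params A [tree_params()] to record on the model.
#' @export
manual_tree <- function(root, params = tree_params()) {
  attrs <- character(0)
  walk <- function(node) {
    if (node$leaf) return(invisible())
    attrs <<- union(attrs, node$attribute)
    walk(node$left)
    walk(node$right)
  }
  walk(root)
  structure(list(root = root, attributes = attrs,
                 classes = names(root$counts), params = params,
                 n_train = root$n, min_leaf_count = 1L),
            class = "eeg_tree")
}
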