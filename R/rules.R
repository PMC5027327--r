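#' Extract classification rules from a tree
#'
#' One rule per leaf, its conditions listed in root-to-leaf order. The
#' rules are mutually exclusive and jointly exhaustive over the attribute
#' space, so exactly one rule fires for any instance.
#'
#' @param model An `eeg_tree`.
#' @return An object of class `eeg_rules`: a list of rules, each a list
#'   with `conditions` (data frame with columns `attribute`, `op` in
#'   \{"<=", ">"\}, `threshold`), `conclusion` (class label) and `support`
#'   (training instances reaching the leaf).
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "eeg_tree"))
  rules <- list()
  walk <- function(node, conds) {
    if (node$leaf) {
      rules[[length(rules) + 1L]] <<- list(
        conditions = conds, conclusion = node$prediction, support = node$n)
      return(invisible())
    }
    cond <- function(op) rbind(conds, data.frame(
      attribute = node$attribute, op = op, threshold = node$threshold,
      stringsAsFactors = FALSE))
    walk(node$left, cond("<="))
    walk(node$right, cond(">"))
  }
  empty <- data.frame(attribute = character(0), op = character(0),
                      threshold = numeric(0), stringsAsFactors = FALSE)
  walk(model$root, empty)
  structure(rules, class = "eeg_rules")
}

.fmt_threshold <- function(x) {
  s <- formatC(x, format = "fg", digits = 6)
  trimws(s)
}

#' @export
format.eeg_rules <- function(x, ...) {
  vapply(x, function(r) {
    lhs <- if (nrow(r$conditions) == 0L) "(always)" else
      paste(sprintf("%s %s %s", r$conditions$attribute, r$conditions$op,
                    .fmt_threshold(r$conditions$threshold)),
            collapse = " and ")
    sprintf("%s: %s (%d)", lhs, r$conclusion, r$support)
  }, character(1))
}

#' @export
print.eeg_rules <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Render a tree as indented text
#'
#' The classic algorithmic representation: one line per branch, children
#' indented with `"|   "`, leaves annotated with their class and support.
#' Thresholds are printed to 3 decimals.
#'
#' @param model An `eeg_tree`.
#' @return Character vector of lines.
#' @export
render_indented <- function(model) {
  stopifnot(inherits(model, "eeg_tree"))
  fmt <- function(t) sprintf("%.3f", t)
  lines <- character(0)
  walk <- function(node, prefix) {
    if (node$leaf) return(invisible())
    for (side in c("left", "right")) {
      op <- if (side == "left") "<=" else ">"
      child <- node[[side]]
      head <- sprintf("%s%s %s %s", prefix, node$attribute, op,
                      fmt(node$threshold))
      if (child$leaf) {
        lines <<- c(lines, sprintf("%s: %s (%d)", head, child$prediction,
                                   child$n))
      } else {
        lines <<- c(lines, head)
        walk(child, paste0(prefix, "|   "))
      }
    }
  }
  if (model$root$leaf) {
    return(sprintf("%s (%d)", model$root$prediction, model$root$n))
  }
  walk(model$root, "")
  lines
}

#' Render a tree in DOT graph format
#'
#' A `digraph` where internal nodes are labeled with their test
#' (threshold to 3 decimals), leaves with their class, and edges with the
#' branch outcome; suitable for Graphviz.
#'
#' @param model An `eeg_tree`.
#' @return A single string of DOT source.
#' @export
render_dot <- function(model) {
  stopifnot(inherits(model, "eeg_tree"))
  fmt <- function(t) sprintf("%.3f", t)
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  counter <- 0L
  walk <- function(node) {
    id <- sprintf("n%d", counter)
    counter <<- counter + 1L
    if (node$leaf) {
      lines <<- c(lines, sprintf("  %s [label=\"%s (%d)\", shape=ellipse];",
                                 id, node$prediction, node$n))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s <= %s\"];",
                                 id, node$attribute, fmt(node$threshold)))
      left_id <- walk(node$left)
      right_id <- walk(node$right)
      lines <<- c(lines,
                  sprintf("  %s -> %s [label=\"yes\"];", id, left_id),
                  sprintf("  %s -> %s [label=\"no\"];", id, right_id))
    }
    id
  }
  walk(model$root)
  paste(c(lines, "}"), collapse = "\n")
}
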