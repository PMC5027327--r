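#' Attribute a tree's splits to brain lobes
#'
#' The interpretive step of the pipeline: every internal node of the tree
#' tests one attribute; electrode attributes are resolved to their lobe
#' through the lobe map, and a lobe is deemed to show significant
#' activity exactly when at least one of its electrodes appears as a
#' split attribute. Non-electrode attributes (such as `Time`) are
#' reported separately and never contribute to a lobe. The depth of the
#' shallowest split per electrode is recorded for inspection but does not
#' affect the presence decision.
#'
#' @param model An `eeg_tree`.
#' @param map A [default_lobe_map()]-style data frame.
#' @return An object of class `lobe_attribution`: list with
#'   `electrodes_used` (named counts), `electrode_depths` (named, 0 =
#'   root), `lobes_present`, `lobes_absent`, `non_channel_attributes`
#'   (named counts), and the `map` used.
#' @export
attribute_tree <- function(model, map = default_lobe_map()) {
  stopifnot(inherits(model, "eeg_tree"))
  electrodes <- integer(0)
  depths <- integer(0)
  non_channel <- integer(0)
  walk <- function(node, depth) {
    if (node$leaf) return(invisible())
    a <- node$attribute
    if (a %in% map$electrode) {
      electrodes[a] <<- (electrodes[a] %||% 0L) + 1L
      depths[a] <<- min(depths[a] %||% depth, depth)
    } else if (.looks_like_electrode(a)) {
      stop("electrode '", a, "' is absent from the lobe map")
    } else {
      non_channel[a] <<- (non_channel[a] %||% 0L) + 1L
    }
    walk(node$left, depth + 1L)
    walk(node$right, depth + 1L)
  }
  walk(model$root, 0L)
  all_lobes <- sort(unique(map$lobe))
  present <- sort(unique(map$lobe[match(names(electrodes), map$electrode)]))
  structure(
    list(electrodes_used = electrodes,
         electrode_depths = depths,
         lobes_present = present,
         lobes_absent = setdiff(all_lobes, present),
         non_channel_attributes = non_channel,
         map = map),
    class = "lobe_attribution"
  )
}

.looks_like_electrode <- function(name) {
  grepl("^[A-Za-z]{1,2}[0-9]{1,2}$|^[A-Za-z]{1,2}z$", name, ignore.case = FALSE)
}

#' @export
print.lobe_attribution <- function(x, ...) {
  cat("<lobe_attribution>\n")
  if (length(x$electrodes_used)) {
    cat("  electrodes:",
        paste(sprintf("%s(%d)", names(x$electrodes_used), x$electrodes_used),
              collapse = ", "), "\n")
  } else {
    cat("  electrodes: none\n")
  }
  cat("  lobes present:",
      if (length(x$lobes_present)) paste(x$lobes_present, collapse = ", ")
      else "none", "\n")
  cat("  lobes absent:",
      if (length(x$lobes_absent)) paste(x$lobes_absent, collapse = ", ")
      else "none", "\n")
  if (length(x$non_channel_attributes))
    cat("  non-channel attributes:",
        paste(names(x$non_channel_attributes), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two attribution reports
#'
#' Differential summary of which lobes carry splits in either of two
#' trees, e.g. one subject group against another.
#'
#' @param a,b `lobe_attribution` reports over the same lobe map.
#' @return List with `shared`, `only_a`, `only_b` (lobe name vectors).
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "lobe_attribution"), inherits(b, "lobe_attribution"))
  if (!identical(a$map, b$map))
    stop("attribution reports use different lobe maps")
  list(shared = intersect(a$lobes_present, b$lobes_present),
       only_a = setdiff(a$lobes_present, b$lobes_present),
       only_b = setdiff(b$lobes_present, a$lobes_present))
}

#' Serialize an attribution report to JSON
#'
#' @param report A `lobe_attribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attribution_json <- function(report, path) {
  stopifnot(inherits(report, "lobe_attribution"))
  jsonlite::write_json(
    list(electrodes_used = as.list(report$electrodes_used),
         electrode_depths = as.list(report$electrode_depths),
         lobes_present = report$lobes_present,
         lobes_absent = report$lobes_absent,
         non_channel_attributes = as.list(report$non_channel_attributes)),
    path, auto_unbox = TRUE)
  invisible(path)
}
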