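#' Balance classes by random undersampling
#'
#' Downsamples every class, uniformly at random and without replacement,
#' to the size of the smallest class, so the tree inducer is not biased
#' toward the majority class. The surviving instances keep their original
#' time order.
#'
#' @param table Feature table data frame.
#' @param seed Integer seed for the random selection.
#' @return Balanced feature table.
#' @export
balance_classes <- function(table, seed = 1L) {
  check_feature_table(table)
  counts <- table(table$Class)
  if (length(counts) < 2L)
    stop("balancing needs at least two classes")
  m <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(cls) {
      idx <- which(table$Class == cls)
      sort(sample(idx, m))
    }))
  })
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Min-max normalize channel columns
#'
#' Independently rescales every channel column to \[0, 1\] by
#' (x - min) / (max - min). A constant column maps to all zeros. The
#' `Time` and `Class` columns are untouched.
#'
#' @param table Feature table data frame.
#' @return Normalized feature table.
#' @export
normalize_minmax <- function(table) {
  check_feature_table(table)
  for (ch in feature_channels(table)) {
    v <- table[[ch]]
    rng <- range(v)
    table[[ch]] <- if (rng[1] == rng[2]) rep(0, length(v))
                   else (v - rng[1]) / (rng[2] - rng[1])
  }
  table
}

#' Group instances into per-channel peaks
#'
#' Temporal aggregation: within each class, consecutive instances (in time
#' order) are partitioned into non-overlapping windows of `window`
#' instances, and each window is reduced to one instance holding the
#' per-channel maximum. The group's `Time` is the latest time in its
#' window; trailing partial windows are dropped. Windows never mix
#' classes, so a balanced table of k instances per class yields exactly
#' floor(k / window) groups per class.
#'
#' @param table Feature table data frame.
#' @param window Instances per group (>= 1).
#' @return Grouped feature table, ordered by `Time`.
#' @export
group_peaks <- function(table, window = 10) {
  check_feature_table(table)
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  chans <- feature_channels(table)
  table <- table[order(table$Time), , drop = FALSE]
  pieces <- lapply(unique(table$Class), function(cls) {
    rows <- table[table$Class == cls, , drop = FALSE]
    k <- nrow(rows) %/% window
    if (k == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(j) {
      w <- rows[((j - 1) * window + 1):(j * window), , drop = FALSE]
      g <- w[1, , drop = FALSE]
      g$Time <- max(w$Time)
      for (ch in chans) g[[ch]] <- max(w[[ch]])
      g
    }))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) stop("no complete window in any class")
  out <- out[order(out$Time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a feature table to a channel subset
#'
#' @param table Feature table data frame.
#' @param names Electrode names to keep, in the desired column order.
#' @return Feature table with only the requested channel columns; `Time`
#'   and `Class` preserved.
#' @export
select_channels <- function(table, names) {
  check_feature_table(table)
  if (length(names) == 0L) stop("channel selection is empty")
  missing <- setdiff(names, feature_channels(table))
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  table[, c("Time", names, "Class"), drop = FALSE]
}

#' Default reduced channel subset
#'
#' A 12-electrode subset spanning all montage lobes, usable to probe
#' whether a reduced montage reaches the same tree structure as the full
#' 32 channels. This particular list is a configurable stand-in, not a
#' canonical choice.
#'
#' @return Character vector of 12 electrode names.
#' @export
default_channel_subset <- function() {
  c("Fp1", "F3", "F7", "Fz", "FT9", "FT10",
    "CP1", "CP2", "P4", "P7", "Pz", "O1")
}
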