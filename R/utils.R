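# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Channel (attribute) columns of a feature table: everything between the
# leading Time column and the trailing Class column.
feature_channels <- function(table) {
  setdiff(names(table), c("Time", "Class"))
}

# Shared validation for feature tables flowing through the pipeline.
check_feature_table <- function(table) {
  if (!is.data.frame(table)) stop("feature table must be a data frame")
  for (col in c("Time", "Class")) {
    if (!col %in% names(table))
      stop("feature table is missing the '", col, "' column")
  }
  if (nrow(table) == 0L) stop("feature table has no instances")
  chans <- feature_channels(table)
  if (length(chans) == 0L) stop("feature table has no channel columns")
  for (ch in chans) {
    if (!is.numeric(table[[ch]]))
      stop("non-numeric values in channel column '", ch, "'")
    if (anyNA(table[[ch]]))
      stop("missing values in channel column '", ch, "'")
  }
  invisible(table)
}
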