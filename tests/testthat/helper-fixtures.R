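# Small, fast fixtures shared across the suite.

# A short, low-rate session on a reduced montage: keeps simulation tests
# well under a second while exercising every code path.
tiny_config <- function(seed = 1L, burst_gain = 3, noise_gain = 1,
                        active = list(ball = "occipital")) {
  montage <- build_default_montage()
  montage <- montage[montage$name %in%
                       c("Fp1", "F3", "Cz", "P3", "Pz", "O1", "Oz", "O2"), ]
  recording_config(
    sampling_rate = 128,
    baseline_band = c(0.3, 45),
    channels = montage,
    epoch_schedule = data.frame(
      label = c("interval", "ball", "interval"),
      duration = c(1, 2, 1), stringsAsFactors = FALSE),
    active_lobes_per_class = active,
    burst_gain = burst_gain, noise_gain = noise_gain,
    seed = seed
  )
}

# Hand-built feature table: deterministic values, arbitrary class sizes.
toy_table <- function(class_sizes, n_channels = 2, seed = 42) {
  classes <- rep(names(class_sizes), times = class_sizes)
  n <- length(classes)
  out <- data.frame(Time = seq_len(n))
  set.seed(seed)
  for (i in seq_len(n_channels))
    out[[paste0("ch", i)]] <- round(runif(n), 4)
  out$Class <- classes
  out
}

# The published-style example tree: Time and one centro-parietal channel.
example_tree <- function() {
  manual_tree(
    tree_split("Time", 14,
      tree_leaf("cube", 4),
      tree_split("Time", 30,
        tree_split("CP1", 0.072,
          tree_leaf("interval", 4),
          tree_leaf("ball", 4)),
        tree_leaf("parallelogram", 4))))
}

# Independent entropy / gain-ratio computation used as a brute-force
# oracle: written against the formulas, not the package internals.
oracle_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_gain_ratio <- function(labels, left_mask) {
  n <- length(labels)
  nl <- sum(left_mask)
  nr <- n - nl
  if (nl == 0 || nr == 0) return(list(gain = 0, ratio = 0))
  gain <- oracle_entropy(labels) -
    (nl / n) * oracle_entropy(labels[left_mask]) -
    (nr / n) * oracle_entropy(labels[!left_mask])
  si <- oracle_entropy(c(rep("l", nl), rep("r", nr)))
  list(gain = gain, ratio = if (si == 0) 0 else gain / si)
}

# Exhaustive best split over every attribute and every midpoint, with the
# package's documented tie-break (earlier column, then lower threshold).
oracle_best_split <- function(tab, min_leaf = 1) {
  attrs <- setdiff(names(tab), "Class")
  best <- NULL
  for (a in attrs) {
    v <- tab[[a]]
    u <- sort(unique(v))
    if (length(u) < 2) next
    for (i in seq_len(length(u) - 1)) {
      thr <- (u[i] + u[i + 1]) / 2
      mask <- v <= thr
      if (sum(mask) < min_leaf || sum(!mask) < min_leaf) next
      g <- oracle_gain_ratio(tab$Class, mask)
      if (g$gain <= 1e-12) next
      if (is.null(best) || g$ratio > best$ratio + 1e-9)
        best <- list(attribute = a, threshold = thr, ratio = g$ratio)
    }
  }
  best
}
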