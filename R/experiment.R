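#' Simulate one subject and run the preprocessing pipeline
#'
#' Convenience wrapper producing the grouped, normalized feature table for
#' a single simulated subject: generate the recording for the subject's
#' profile, run the filter chain, balance the classes, min-max normalize,
#' peak-group, and optionally restrict the channels. With the default
#' schedule this yields 40 balanced instances for each of the four
#' classes (ball, cube, parallelogram, interval) and a 16-instance
#' grouped table.
#'
#' @param profile `"sighted"` or `"blind"` (see [subject_profile()]), or a
#'   named list mapping classes to lobes.
#' @param seed Integer seed driving both the recording and the balancing.
#' @param spec A [filter_spec()].
#' @param buffer_size Preprocessing buffer size (samples per instance).
#' @param group_window Instances per peak group.
#' @param channel_subset Optional electrode names to retain before
#'   grouping.
#' @param burst_gain,noise_gain Passed to [recording_config()].
#' @return A grouped feature table data frame.
#' @export
simulate_subject_features <- function(profile = "sighted", seed = 1L,
                                      spec = filter_spec(),
                                      buffer_size = 32, group_window = 10,
                                      channel_subset = NULL,
                                      burst_gain = 3, noise_gain = 1) {
  lobes <- if (is.character(profile) && length(profile) == 1L)
    subject_profile(profile) else profile
  config <- recording_config(active_lobes_per_class = lobes, seed = seed,
                             burst_gain = burst_gain, noise_gain = noise_gain)
  rec <- generate_recording(config)
  ft <- to_feature_table(rec, spec, buffer_size)
  ft <- balance_classes(ft, seed = seed)
  ft <- normalize_minmax(ft)
  if (!is.null(channel_subset)) ft <- select_channels(ft, channel_subset)
  group_peaks(ft, group_window)
}

#' Configure a multi-subject experiment
#'
#' @param subjects Data frame with columns `id`, `profile` (`"sighted"` or
#'   `"blind"`) and `seed`; ids must be unique.
#' @param tree_params_list List of [tree_params()] to sweep per subject
#'   (e.g. minimum leaf fractions 0.01, 0.05, 0.10).
#' @param group_window Instances per peak group.
#' @param channel_subset Optional electrode subset applied to every
#'   subject.
#' @param output_dir Directory receiving all per-subject artifacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(subjects,
                              tree_params_list = list(tree_params(0.01)),
                              group_window = 10,
                              channel_subset = NULL,
                              output_dir = tempfile("neurotree_exp")) {
  if (!is.data.frame(subjects) || nrow(subjects) == 0L)
    stop("experiment needs at least one subject")
  for (col in c("id", "profile", "seed"))
    if (!col %in% names(subjects))
      stop("subjects table is missing the '", col, "' column")
  if (anyDuplicated(subjects$id)) stop("subject ids must be unique")
  if (length(tree_params_list) == 0L)
    stop("need at least one tree parameter set")
  structure(list(subjects = subjects, tree_params_list = tree_params_list,
                 group_window = group_window,
                 channel_subset = channel_subset,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run a full multi-subject experiment
#'
#' For every subject: simulate the recording, preprocess and prepare the
#' grouped feature table (written as CSV), then for every tree parameter
#' set induce a tree and write its indented text, DOT source, extracted
#' rules and lobe-attribution report. A cross-subject comparison table of
#' lobes present (first parameter set) and a JSON manifest recording all
#' seeds, parameters and output files complete the run.
#'
#' @param config An [experiment_config()].
#' @return The manifest, invisibly: list with per-subject entries and the
#'   comparison data frame.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- config$subjects
  manifest <- list(subjects = list(), parameters = list(
    group_window = config$group_window,
    channel_subset = config$channel_subset,
    tree_params = lapply(config$tree_params_list, unclass)))
  comparison <- list()

  for (i in seq_len(nrow(subjects))) {
    id <- as.character(subjects$id[i])
    profile <- as.character(subjects$profile[i])
    seed <- as.integer(subjects$seed[i])
    stage <- "simulate+prepare"
    entry <- tryCatch({
      grouped <- simulate_subject_features(
        profile, seed, group_window = config$group_window,
        channel_subset = config$channel_subset)
      grouped_path <- file.path(config$output_dir,
                                paste0(id, "_grouped.csv"))
      write_feature_csv(grouped, grouped_path)
      files <- list(grouped = grouped_path)
      reports <- list()
      for (j in seq_along(config$tree_params_list)) {
        stage <- sprintf("tree[%d]", j)
        tp <- config$tree_params_list[[j]]
        model <- induce_tree(grouped, tp)
        tag <- sprintf("%s_minleaf%g", id, tp$min_leaf_fraction)
        txt <- file.path(config$output_dir, paste0(tag, ".txt"))
        writeLines(render_indented(model), txt)
        dot <- file.path(config$output_dir, paste0(tag, ".dot"))
        writeLines(render_dot(model), dot)
        rules <- file.path(config$output_dir, paste0(tag, "_rules.txt"))
        writeLines(format(extract_rules(model)), rules)
        stage <- sprintf("attribute[%d]", j)
        report <- attribute_tree(model)
        attr_path <- file.path(config$output_dir,
                               paste0(tag, "_attribution.json"))
        write_attribution_json(report, attr_path)
        files[[tag]] <- c(tree = txt, dot = dot, rules = rules,
                          attribution = attr_path)
        reports[[j]] <- report
      }
      comparison[[id]] <- list(profile = profile,
                               lobes = reports[[1]]$lobes_present)
      list(id = id, profile = profile, seed = seed, files = files,
           n_grouped = nrow(grouped), status = "ok")
    }, error = function(e) {
      warning("subject '", id, "' failed at stage ", stage, ": ",
              conditionMessage(e), call. = FALSE)
      list(id = id, profile = profile, seed = seed, status = "failed",
           stage = stage, message = conditionMessage(e))
    })
    manifest$subjects[[id]] <- entry
  }

  all_lobes <- sort(unique(default_lobe_map()$lobe))
  ok_ids <- names(comparison)
  if (length(ok_ids)) {
    cmp <- data.frame(
      subject = ok_ids,
      profile = vapply(comparison, `[[`, character(1), "profile"),
      stringsAsFactors = FALSE
    )
    for (lb in all_lobes)
      cmp[[lb]] <- vapply(comparison,
                          function(x) lb %in% x$lobes, logical(1))
    rownames(cmp) <- NULL
    cmp_path <- file.path(config$output_dir, "lobe_comparison.csv")
    write.csv(cmp, cmp_path, row.names = FALSE)
    manifest$comparison <- cmp
    manifest$files <- list(comparison = cmp_path)
  }
  jsonlite::write_json(
    manifest_to_json(manifest),
    file.path(config$output_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

manifest_to_json <- function(manifest) {
  m <- manifest
  if (!is.null(m$comparison)) m$comparison <- as.list(m$comparison)
  m
}

#' Read an experiment configuration from YAML
#'
#' Expects top-level keys `subjects` (list of `id`/`profile`/`seed`
#' mappings), and optionally `group_window`, `channel_subset`,
#' `min_leaf_fractions` and `output_dir`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  subjects <- do.call(rbind, lapply(y$subjects, function(s)
    data.frame(id = s$id, profile = s$profile, seed = s$seed,
               stringsAsFactors = FALSE)))
  fracs <- y$min_leaf_fractions
  if (is.null(fracs)) fracs <- 0.01
  experiment_config(
    subjects = subjects,
    tree_params_list = lapply(fracs, function(f) tree_params(f)),
    group_window = y$group_window %||% 10,
    channel_subset = unlist(y$channel_subset),
    output_dir = y$output_dir %||% tempfile("neurotree_exp")
  )
}
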