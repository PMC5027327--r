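#' Parse a 10-20 system electrode name
#'
#' Splits an electrode label into its letter prefix (the scalp region code)
#' and its hemisphere, following the 10-20 convention: a trailing "z" marks
#' the midline, odd digits the left hemisphere and even digits the right.
#'
#' @param name A single electrode label, e.g. `"Fp1"`, `"Oz"`, `"CP2"`.
#' @return A list with components `prefix` (character) and `hemisphere`
#'   (one of `"left"`, `"right"`, `"midline"`).
#' @examples
#' parse_channel_name("Fp1")  # prefix "Fp", left
#' parse_channel_name("Oz")   # prefix "O", midline
#' @export
parse_channel_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("'name' must be a single electrode label")
  m <- regmatches(name, regexec("^([A-Za-z]+?)([0-9]+|[zZ])$", name))[[1]]
  if (length(m) == 0L)
    stop("malformed electrode name: '", name,
         "' (expected letters followed by digits or 'z')")
  prefix <- m[2]
  suffix <- m[3]
  hemisphere <- if (grepl("^[zZ]$", suffix)) {
    "midline"
  } else if (as.integer(suffix) %% 2L == 1L) {
    "left"
  } else {
    "right"
  }
  list(prefix = prefix, hemisphere = hemisphere)
}

# Region code -> lobe. C (central sulcus) and CP are not in the classic
# four-lobe table but carry montage channels, so they get their own rows:
# C -> central, CP -> parietal (CP electrodes sit over the parietal cortex).
.prefix_lobes <- c(
  Fp = "frontal", AF = "frontal", F = "frontal", FC = "frontal",
  FT = "frontal",
  T = "temporal", TP = "temporal",
  C = "central",
  CP = "parietal", P = "parietal",
  PO = "occipital", O = "occipital"
)

#' Lobe of a 10-20 electrode
#'
#' @param name Electrode label.
#' @return One of `"frontal"`, `"temporal"`, `"parietal"`, `"occipital"`,
#'   `"central"`.
#' @keywords internal
channel_lobe <- function(name) {
  prefix <- parse_channel_name(name)$prefix
  lobe <- .prefix_lobes[[prefix]]
  if (is.null(lobe))
    stop("unknown electrode region prefix: '", prefix, "' in '", name, "'")
  lobe
}

#' Build the default 32-channel montage
#'
#' The standard 32-electrode active-cap layout of the 10-20 system, ordered
#' front to back. Each channel is annotated with its brain lobe (frontal,
#' temporal, central, parietal, occipital) and hemisphere (left, right,
#' midline).
#'
#' @return A data frame with columns `name`, `lobe`, `hemisphere`; exactly
#'   32 rows, unique names.
#' @examples
#' m <- build_default_montage()
#' subset(m, lobe == "occipital")$name  # O1, Oz, O2
#' @export
build_default_montage <- function() {
  names <- c(
    "Fp1", "Fp2",
    "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "FT9", "FT10",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2"
  )
  data.frame(
    name = names,
    lobe = vapply(names, channel_lobe, character(1), USE.NAMES = FALSE),
    hemisphere = vapply(names, function(n) parse_channel_name(n)$hemisphere,
                        character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# Functional annotations per lobe, used in the lobe map's notes column.
.lobe_functions <- c(
  frontal   = "executive function, cognition, motor planning, speech",
  temporal  = "audition, perception of biological motion",
  parietal  = "somatosensory perception, spatial representation, touch",
  occipital = "vision and visual imagery",
  central   = "sensorimotor cortex over the central sulcus"
)

#' Electrode-to-lobe map
#'
#' Maps every montage electrode to its brain lobe with a short functional
#' note, the basis for attributing decision-tree splits to cortical
#' regions.
#'
#' @param montage A montage data frame as returned by
#'   [build_default_montage()].
#' @return A data frame of class `lobe_map` with columns `electrode`,
#'   `lobe`, `note`.
#' @export
default_lobe_map <- function(montage = build_default_montage()) {
  map <- data.frame(
    electrode = montage$name,
    lobe = montage$lobe,
    note = unname(.lobe_functions[montage$lobe]),
    stringsAsFactors = FALSE
  )
  class(map) <- c("lobe_map", "data.frame")
  map
}
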