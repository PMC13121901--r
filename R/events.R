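## Core containers: channel panel, per-event intensity matrix, sample
## metadata and study set. Deliberately light S3 lists over a base matrix --
## the pipeline moves a lot of events around and plain matrices keep that
## cheap and transparent.

#' Channel panel
#'
#' Ordered set of measured channels (markers) with optional fluorophore
#' labels. The reference panel of this package is CD45, CD31, PDPN, ICAM1,
#' VCAM1 -- the minimal lymph-node stromal cell panel.
#'
#' @param channels character vector of unique channel names.
#' @param fluorophores optional character vector of the same length.
#' @return a `channel_panel` object.
#' @export
channel_panel <- function(channels, fluorophores = NULL) {
  channels <- as.character(channels)
  if (length(channels) == 0)
    cc_stop("panel must contain at least one channel", "cc_panel_error")
  if (anyDuplicated(channels))
    cc_stop("duplicate channel names in panel", "cc_panel_error")
  if (!is.null(fluorophores) && length(fluorophores) != length(channels))
    cc_stop("fluorophores must match channels in length", "cc_panel_error")
  structure(list(channels = channels, fluorophores = fluorophores),
            class = "channel_panel")
}

#' Reference five-marker stromal panel
#' @return a `channel_panel` with CD45, CD31, PDPN, ICAM1, VCAM1.
#' @export
reference_panel <- function() {
  channel_panel(c("CD45", "CD31", "PDPN", "ICAM1", "VCAM1"),
                c("PE-Cy7", "BV605", "BV421", "PE", "AF647"))
}

#' @export
print.channel_panel <- function(x, ...) {
  cat("<channel_panel> ", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Event matrix
#'
#' Per-event channel intensities: an `n_events x n_channels` numeric matrix
#' tied to a [channel_panel()] and a scale flag (`"linear"` measured
#' intensities, or `"transformed"` after [apply_transform()]).
#'
#' @param values numeric matrix (rows = events); column names, if present,
#'   must match the panel.
#' @param panel a `channel_panel`.
#' @param scale `"linear"` or `"transformed"`.
#' @return an `event_matrix` object with fields `values`, `panel`, `scale`.
#' @export
event_matrix <- function(values, panel, scale = c("linear", "transformed")) {
  scale <- match.arg(scale)
  if (!inherits(panel, "channel_panel")) panel <- channel_panel(panel)
  values <- as.matrix(values)
  if (nrow(values) == 0) {
    values <- matrix(numeric(0), 0, length(panel$channels))
  }
  if (ncol(values) != length(panel$channels))
    cc_stop("column count does not match panel size", "cc_panel_error")
  if (anyNA(values) || any(!is.finite(values)))
    cc_stop("event matrix contains missing or non-finite values", "cc_format_error")
  storage.mode(values) <- "double"
  colnames(values) <- panel$channels
  structure(list(values = values, panel = panel, scale = scale),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %d events x %d channels (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Number of events in an event matrix
#' @param m an `event_matrix`.
#' @return integer event count.
#' @export
n_events <- function(m) nrow(m$values)

#' Channel names of an event matrix or study set
#' @param x an `event_matrix`, `channel_panel` or `study_set`.
#' @return character vector of channel names.
#' @export
channels <- function(x) {
  if (inherits(x, "channel_panel")) return(x$channels)
  if (inherits(x, "event_matrix")) return(x$panel$channels)
  if (inherits(x, "study_set")) return(x$samples[[1]]$events$panel$channels)
  cc_stop("no channels for this object", "cc_parameter_error")
}

#' Sample metadata
#'
#' @param sample_id character id.
#' @param sample_type one of `"bead_single_stain"`, `"unlabeled_cells"`,
#'   `"labeled_cells"`.
#' @param stain_channel stained channel name; required for (and only allowed
#'   on) bead single-stain samples.
#' @param day acquisition day / batch index (integer).
#' @param passage passage number; required for (and only allowed on) labeled
#'   cell samples.
#' @return a `sample_meta` object.
#' @export
sample_meta <- function(sample_id, sample_type, stain_channel = NA_character_,
                        day, passage = NA_integer_) {
  sample_type <- match.arg(sample_type,
                           c("bead_single_stain", "unlabeled_cells", "labeled_cells"))
  if (sample_type == "bead_single_stain" && is.na(stain_channel))
    cc_stop("bead single-stain sample requires a stain_channel", "cc_parameter_error")
  if (sample_type != "bead_single_stain" && !is.na(stain_channel))
    cc_stop("stain_channel only valid for bead single-stain samples", "cc_parameter_error")
  if (sample_type == "labeled_cells" && is.na(passage))
    cc_stop("labeled cell sample requires a passage", "cc_parameter_error")
  if (sample_type != "labeled_cells" && !is.na(passage))
    cc_stop("passage only valid for labeled cell samples", "cc_parameter_error")
  structure(list(sample_id = as.character(sample_id), sample_type = sample_type,
                 stain_channel = as.character(stain_channel),
                 day = as.integer(day), passage = as.integer(passage)),
            class = "sample_meta")
}

#' Study set
#'
#' The unit the pipeline consumes: a list of samples, each a
#' `list(meta = sample_meta, events = event_matrix)`, all sharing one panel.
#'
#' @param samples list of `list(meta=, events=)` pairs.
#' @return a `study_set` object.
#' @export
study_set <- function(samples) {
  if (length(samples) == 0)
    cc_stop("study set must contain at least one sample", "cc_parameter_error")
  ch <- lapply(samples, function(s) s$events$panel$channels)
  if (!all(vapply(ch, identical, logical(1), ch[[1]])))
    cc_stop("all samples in a study must share one panel", "cc_panel_error")
  ids <- vapply(samples, function(s) s$meta$sample_id, character(1))
  if (anyDuplicated(ids))
    cc_stop("duplicate sample ids in study", "cc_parameter_error")
  structure(list(samples = samples), class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set> %d samples, %d channels\n",
              length(x$samples), length(channels(x))))
  for (s in x$samples) {
    cat(sprintf("  %-22s %-17s day %d  %6d events%s\n", s$meta$sample_id,
                s$meta$sample_type, s$meta$day, n_events(s$events),
                if (!is.na(s$meta$passage)) sprintf("  P%d", s$meta$passage) else ""))
  }
  invisible(x)
}

## Helpers over study sets ---------------------------------------------------

study_samples <- function(study, sample_type = NULL, day = NULL,
                          stain_channel = NULL) {
  keep <- vapply(study$samples, function(s) {
    ok <- TRUE
    if (!is.null(sample_type)) ok <- ok && s$meta$sample_type %in% sample_type
    if (!is.null(day)) ok <- ok && s$meta$day %in% day
    if (!is.null(stain_channel)) ok <- ok && identical(s$meta$stain_channel, stain_channel)
    ok
  }, logical(1))
  study$samples[keep]
}

study_days <- function(study) {
  sort(unique(vapply(study$samples, function(s) s$meta$day, integer(1))))
}
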