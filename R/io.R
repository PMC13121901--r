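## Event table IO, scale transform and dataset-variant assembly.

#' Read event data from file
#'
#' @param path path to a CSV (header row of channel names, one row per
#'   event) or FCS 3.0/3.1 file.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @return an [event_matrix()] on the linear scale.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) cc_stop(paste0("no such file: ", path), "cc_format_error")
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "fcs") return(read_fcs(path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE, comment.char = "#"),
                 error = function(e) cc_stop(paste0("unreadable CSV: ", conditionMessage(e)),
                                             "cc_format_error"))
  if (anyDuplicated(names(df)))
    cc_stop("duplicate channel names in CSV header", "cc_panel_error")
  if (!all(vapply(df, is.numeric, logical(1))))
    cc_stop("non-numeric columns in event CSV", "cc_format_error")
  event_matrix(as.matrix(df), channel_panel(names(df)), scale = "linear")
}

#' Write an event matrix as CSV
#'
#' @param m an [event_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m$values), path, row.names = FALSE)
  invisible(path)
}

#' Arcsinh transform specification
#'
#' The display/analysis transform for fluorescence intensities:
#' `asinh(value / cofactor)`. Near zero it is linear (so the negative values
#' compensation can produce stay finite and ordered), at high intensity it is
#' logarithmic. The default cofactor of 150 suits conventional-cytometer
#' fluorescence scales.
#'
#' @param kind only `"arcsinh"`.
#' @param cofactor positive scale cofactor; scalar or one value per channel.
#' @return a `transform_spec` object.
#' @export
transform_spec <- function(kind = "arcsinh", cofactor = 150) {
  kind <- match.arg(kind)
  if (any(!is.finite(cofactor)) || any(cofactor <= 0))
    cc_stop("cofactor must be positive", "cc_parameter_error")
  structure(list(kind = kind, cofactor = cofactor), class = "transform_spec")
}

#' Apply a scale transform to an event matrix
#'
#' @param m an [event_matrix()] on the linear scale.
#' @param t a [transform_spec()]; the cofactor is recycled across channels
#'   when scalar.
#' @return an `event_matrix` with `scale = "transformed"`.
#' @export
apply_transform <- function(m, t = transform_spec()) {
  if (!inherits(m, "event_matrix")) cc_stop("m must be an event_matrix", "cc_parameter_error")
  if (m$scale != "linear")
    cc_stop("apply_transform expects linear-scale input", "cc_parameter_error")
  cf <- t$cofactor
  if (length(cf) == 1) cf <- rep(cf, ncol(m$values))
  if (length(cf) != ncol(m$values))
    cc_stop("cofactor length must be 1 or the number of channels", "cc_parameter_error")
  v <- sweep(m$values, 2, cf, "/")
  event_matrix(asinh(v), m$panel, scale = "transformed")
}

#' Dataset variant (sample-combination) specification
#'
#' Which samples, events and channels enter a pooled analysis dataset:
#' whether bead controls are included (and capped), whether cell samples are
#' capped to the smallest sample ("limited"), whether only CD45-negative
#' events are kept, and whether the CD45 channel is dropped afterwards.
#'
#' @param include_beads `"none"`, `"all"` or `"limited"`.
#' @param cells `"all"`, `"limited"`, `"gated_cd45neg"` or
#'   `"gated_cd45neg_limited"`.
#' @param drop_cd45_channel drop the CD45 column; only allowed for the
#'   CD45-negative gated variants.
#' @return a `dataset_variant` object.
#' @export
dataset_variant <- function(include_beads = c("all", "none", "limited"),
                            cells = c("all", "limited", "gated_cd45neg",
                                      "gated_cd45neg_limited"),
                            drop_cd45_channel = FALSE) {
  include_beads <- match.arg(include_beads)
  cells <- match.arg(cells)
  gated <- cells %in% c("gated_cd45neg", "gated_cd45neg_limited")
  if (drop_cd45_channel && !gated)
    cc_stop("drop_cd45_channel only valid for CD45-negative gated variants",
            "cc_parameter_error")
  structure(list(include_beads = include_beads, cells = cells,
                 drop_cd45_channel = drop_cd45_channel, gated = gated),
            class = "dataset_variant")
}

#' Assemble a pooled analysis dataset from a study
#'
#' Concatenates the selected samples into one event matrix with per-event
#' provenance. "Limited" groups are downsampled uniformly without
#' replacement to the smallest included sample's (post-gating) size;
#' CD45-negative gating keeps events with CD45 below `cd45_threshold`
#' (applied to every included sample, beads included).
#'
#' @param study a [study_set()].
#' @param variant a [dataset_variant()].
#' @param cd45_threshold linear-scale CD45 cutoff; required for gated
#'   variants.
#' @param seed integer seed controlling the downsampling.
#' @param cd45_channel channel name used for the gate.
#' @return an `assembled_dataset`: `events` ([event_matrix()]) plus aligned
#'   per-event vectors `sample_id`, `sample_type`, `stain_channel`, `day`,
#'   `passage`, and the `variant` and `seed` used.
#' @export
assemble_dataset <- function(study, variant, cd45_threshold = NULL, seed = 1L,
                             cd45_channel = "CD45") {
  if (variant$gated && is.null(cd45_threshold))
    cc_stop("CD45-negative variants require cd45_threshold", "cc_parameter_error")
  ch <- channels(study)
  if (variant$gated && !cd45_channel %in% ch)
    cc_stop(paste0("channel ", cd45_channel, " not in panel"), "cc_panel_error")

  keep <- list()
  for (s in study$samples) {
    is_bead <- s$meta$sample_type == "bead_single_stain"
    if (is_bead && variant$include_beads == "none") next
    v <- s$events$values
    if (variant$gated) v <- v[v[, cd45_channel] < cd45_threshold, , drop = FALSE]
    mode <- if (is_bead) variant$include_beads else
      if (variant$cells %in% c("limited", "gated_cd45neg_limited")) "limited" else "all"
    keep[[length(keep) + 1]] <- list(meta = s$meta, values = v, mode = mode)
  }
  if (length(keep) == 0 || sum(vapply(keep, function(k) nrow(k$values), integer(1))) == 0)
    cc_stop("dataset variant selects no events", "cc_assembly_error")

  sizes <- vapply(keep, function(k) nrow(k$values), integer(1))
  smallest <- min(sizes)
  seeds <- derive_seeds(seed, length(keep))
  parts <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    v <- keep[[i]]$values
    if (keep[[i]]$mode == "limited" && nrow(v) > smallest) {
      idx <- with_seed(seeds[i], sample.int(nrow(v), smallest))
      v <- v[sort(idx), , drop = FALSE]
    }
    parts[[i]] <- v
  }
  values <- do.call(rbind, parts)
  ns <- vapply(parts, nrow, integer(1))
  meta_of <- function(f, typ) {
    unlist(lapply(seq_along(keep), function(i) rep(f(keep[[i]]$meta), ns[i])))
  }
  panel <- study$samples[[1]]$events$panel
  if (variant$drop_cd45_channel) {
    values <- values[, setdiff(ch, cd45_channel), drop = FALSE]
    panel <- channel_panel(setdiff(ch, cd45_channel))
  }
  if (nrow(values) == 0) cc_stop("dataset variant selects no events", "cc_assembly_error")
  structure(list(
    events = event_matrix(values, panel, scale = study$samples[[1]]$events$scale),
    sample_id = meta_of(function(m) m$sample_id),
    sample_type = meta_of(function(m) m$sample_type),
    stain_channel = meta_of(function(m) m$stain_channel),
    day = as.integer(meta_of(function(m) m$day)),
    passage = as.integer(meta_of(function(m) m$passage)),
    variant = variant, seed = seed
  ), class = "assembled_dataset")
}

#' @export
print.assembled_dataset <- function(x, ...) {
  cat(sprintf("<assembled_dataset> %d events from %d samples (beads: %s, cells: %s%s)\n",
              n_events(x$events), length(unique(x$sample_id)),
              x$variant$include_beads, x$variant$cells,
              if (x$variant$drop_cd45_channel) ", CD45 channel dropped" else ""))
  invisible(x)
}

#' Export an assembled dataset as CSV with provenance header
#'
#' Writes the event values plus a `sample_id` column, preceded by `#`
#' comment lines recording the variant and seed.
#'
#' @param ad an `assembled_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembled_csv <- function(ad, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# assembled dataset: beads=%s cells=%s drop_cd45=%s seed=%d",
            ad$variant$include_beads, ad$variant$cells,
            ad$variant$drop_cd45_channel, ad$seed),
    sprintf("# scale=%s n_events=%d", ad$events$scale, n_events(ad$events))
  ), con)
  df <- data.frame(sample_id = ad$sample_id, ad$events$values, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
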