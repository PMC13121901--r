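## Sequential ("layered") gating. Layer 1 removes CD45-positive events with
## a threshold placed so that a chosen fraction of the unlabeled control
## events stays inside the negative gate; layer 2 splits the CD45-negative
## events into the four main stromal populations by CD31/PDPN quadrants;
## layer 3 subdivides the reticular and double-negative populations by
## ICAM1/VCAM1. The variation study repeats the whole cascade under
## different retention criteria and summarizes, per population, the
## coefficient of variation of the resulting counts -- the robustness
## baseline the consensus method is compared against.

#' Gating criteria
#'
#' @param retention fraction of unlabeled control events that must remain
#'   inside the negative gate (the published variants are 0.995, 0.999 and
#'   1.0).
#' @param boundary_style `"axis_aligned"` (default) or `"oblique"`.
#' @param margin multiplicative perturbation applied to every threshold, to
#'   emulate a user dragging gates (1 = none).
#' @return a `gating_criteria` object.
#' @export
gating_criteria <- function(retention, boundary_style = c("axis_aligned", "oblique"),
                            margin = 1) {
  boundary_style <- match.arg(boundary_style)
  if (retention <= 0 || retention > 1)
    cc_stop("retention must be in (0, 1]", "cc_parameter_error")
  if (margin <= 0) cc_stop("margin must be positive", "cc_parameter_error")
  structure(list(retention = retention, boundary_style = boundary_style,
                 margin = margin), class = "gating_criteria")
}

#' Quantile gate from negative-control events
#'
#' The cutoff is the smallest value such that at least `retention` of the
#' control events are at or below it; with several control samples the
#' constraint must hold for each, so the per-sample cutoffs are maximized.
#'
#' @param neg_values numeric vector, or list of vectors (one per control
#'   sample).
#' @param retention retention fraction in (0, 1].
#' @param channel channel name for bookkeeping.
#' @return a `gate_threshold` with fields `channel`, `cutoff`,
#'   `retention_used`.
#' @export
quantile_gate <- function(neg_values, retention, channel = NA_character_) {
  if (!is.list(neg_values)) neg_values <- list(neg_values)
  if (any(vapply(neg_values, length, integer(1)) == 0))
    cc_stop("empty negative-control values", "cc_parameter_error")
  cutoffs <- vapply(neg_values, function(v) {
    s <- sort(v)
    s[ceiling(retention * length(s))]
  }, numeric(1))
  structure(list(channel = channel, cutoff = max(cutoffs),
                 retention_used = retention), class = "gate_threshold")
}

#' Quadrant gate on two channels
#'
#' Axis-aligned: four quadrants split at the two cutoffs. Oblique: the
#' negative region is the set of points with non-positive cross product
#' relative to the directed line `p1 -> p2` (mirroring diagonal
#' double-negative gates); remaining events take their axis-aligned
#' quadrant, and points above the line but below both cutoffs are assigned
#' to the single-positive quadrant they exceed most nearly.
#'
#' @param x,y numeric vectors of the two channels.
#' @param tx,ty [quantile_gate()] thresholds for x and y.
#' @param style `"axis_aligned"` or `"oblique"`.
#' @param line for oblique gates, `list(p1 = c(x, y), p2 = c(x, y))`.
#' @return factor with levels `neg`, `x_pos`, `y_pos`, `double_pos`.
#' @export
quadrant_gate <- function(x, y, tx, ty, style = c("axis_aligned", "oblique"),
                          line = NULL) {
  style <- match.arg(style)
  xpos <- x > tx$cutoff
  ypos <- y > ty$cutoff
  lab <- ifelse(xpos & ypos, "double_pos",
         ifelse(xpos, "x_pos", ifelse(ypos, "y_pos", "neg")))
  if (style == "oblique") {
    if (is.null(line)) cc_stop("oblique gate requires a line", "cc_parameter_error")
    p1 <- line$p1; p2 <- line$p2
    if (isTRUE(all.equal(p1, p2)))
      cc_stop("degenerate oblique line: coincident points", "cc_parameter_error")
    s <- (p2[1] - p1[1]) * (y - p1[2]) - (p2[2] - p1[2]) * (x - p1[1])
    lab[s <= 0] <- "neg"
    orphan <- s > 0 & lab == "neg"
    lab[orphan] <- ifelse((x - tx$cutoff)[orphan] >= (y - ty$cutoff)[orphan],
                          "x_pos", "y_pos")
  }
  factor(lab, levels = c("neg", "x_pos", "y_pos", "double_pos"))
}

## layer-2 quadrant -> population name (x = CD31, y = PDPN)
layer2_map <- c(neg = "PvC_DN", x_pos = "BEC", y_pos = "FRC", double_pos = "LEC")

#' Sequential three-layer gating of a study
#'
#' Thresholds come from the unlabeled control samples at the criteria's
#' retention (each layer's thresholds from the control events surviving the
#' previous layer); labels are assigned to the labeled-cell events. Terminal
#' labels partition the events: `CD45pos`, `BEC`, `LEC`, and ICAM1/VCAM1
#' quadrant sublabels within `FRC` and `PvC_DN`.
#'
#' @param study a [study_set()] containing unlabeled and labeled samples.
#' @param criteria a [gating_criteria()].
#' @return a `gating_result`: per-event `labels` (terminal), `layer1`,
#'   `layer2`, aligned `sample_id`/`day`/`passage`, the thresholds used and
#'   per-population `counts`.
#' @export
sequential_gating <- function(study, criteria = gating_criteria(0.999)) {
  ch <- channels(study)
  need <- c("CD45", "CD31", "PDPN", "ICAM1", "VCAM1")
  if (!all(need %in% ch))
    cc_stop(paste0("panel lacks required channels: ",
                   paste(setdiff(need, ch), collapse = ", ")), "cc_panel_error")
  unl <- study_samples(study, "unlabeled_cells")
  lab <- study_samples(study, "labeled_cells")
  if (length(unl) == 0 || length(lab) == 0)
    cc_stop("study must contain unlabeled and labeled samples", "cc_parameter_error")
  mg <- criteria$margin

  ## layer 1: CD45
  t_cd45 <- quantile_gate(lapply(unl, function(s) s$events$values[, "CD45"]),
                          criteria$retention, "CD45")
  t_cd45$cutoff <- t_cd45$cutoff * mg
  unl_gated <- lapply(unl, function(s)
    s$events$values[s$events$values[, "CD45"] <= t_cd45$cutoff, , drop = FALSE])

  ## layer 2: CD31 / PDPN thresholds from CD45-negative control events
  t_cd31 <- quantile_gate(lapply(unl_gated, function(v) v[, "CD31"]),
                          criteria$retention, "CD31")
  t_pdpn <- quantile_gate(lapply(unl_gated, function(v) v[, "PDPN"]),
                          criteria$retention, "PDPN")
  t_icam <- quantile_gate(lapply(unl_gated, function(v) v[, "ICAM1"]),
                          criteria$retention, "ICAM1")
  t_vcam <- quantile_gate(lapply(unl_gated, function(v) v[, "VCAM1"]),
                          criteria$retention, "VCAM1")
  for (t_ in c("t_cd31", "t_pdpn", "t_icam", "t_vcam"))
    assign(t_, within_margin(get(t_), mg))

  v <- do.call(rbind, lapply(lab, function(s) s$events$values))
  ns <- vapply(lab, function(s) n_events(s$events), integer(1))
  sample_id <- rep(vapply(lab, function(s) s$meta$sample_id, character(1)), ns)
  day <- rep(vapply(lab, function(s) s$meta$day, integer(1)), ns)
  passage <- rep(vapply(lab, function(s) s$meta$passage, integer(1)), ns)

  layer1 <- ifelse(v[, "CD45"] > t_cd45$cutoff, "CD45pos", "CD45neg")
  layer2 <- rep(NA_character_, nrow(v))
  neg <- layer1 == "CD45neg"
  q2 <- quadrant_gate(v[neg, "CD31"], v[neg, "PDPN"], t_cd31, t_pdpn)
  layer2[neg] <- layer2_map[as.character(q2)]

  labels <- layer1
  labels[neg] <- layer2[neg]
  for (pop in c("FRC", "PvC_DN")) {
    in_pop <- !is.na(layer2) & layer2 == pop
    if (!any(in_pop)) next
    q3 <- quadrant_gate(v[in_pop, "ICAM1"], v[in_pop, "VCAM1"], t_icam, t_vcam)
    sub <- c(neg = "ICAM1neg_VCAM1neg", x_pos = "ICAM1pos_VCAM1neg",
             y_pos = "ICAM1neg_VCAM1pos", double_pos = "ICAM1pos_VCAM1pos")
    labels[in_pop] <- paste0(pop, "_", sub[as.character(q3)])
  }
  thresholds <- data.frame(
    channel = c("CD45", "CD31", "PDPN", "ICAM1", "VCAM1"),
    cutoff = c(t_cd45$cutoff, t_cd31$cutoff, t_pdpn$cutoff,
               t_icam$cutoff, t_vcam$cutoff),
    retention_used = criteria$retention, margin = mg)
  structure(list(labels = labels, layer1 = layer1, layer2 = layer2,
                 sample_id = sample_id, day = day, passage = passage,
                 thresholds = thresholds, criteria = criteria,
                 counts = table(labels)), class = "gating_result")
}

within_margin <- function(t_, mg) { t_$cutoff <- t_$cutoff * mg; t_ }

#' Gate-placement variation study
#'
#' Runs the sequential gating once per criteria variant and summarizes, per
#' terminal population, the coefficient of variation of the event counts
#' across variants (sample SD / mean, %), plus the mean CV per gating layer
#' to expose how placement variation compounds down the hierarchy.
#'
#' @param study a [study_set()].
#' @param criteria list of at least two [gating_criteria()].
#' @return list with `counts` (populations x criteria), `cv` per
#'   population (`NA` when absent under every criterion), `mean_cv`, and
#'   `layer_mean_cv` (layers 1-3).
#' @export
gating_variation_study <- function(study, criteria) {
  if (length(criteria) < 2)
    cc_stop("variation study requires at least two criteria", "cc_parameter_error")
  runs <- lapply(criteria, function(cr) sequential_gating(study, cr))
  count_matrix <- function(label_list) {
    labs <- sort(unique(unlist(label_list)))
    out <- sapply(label_list, function(l) table(factor(l, levels = labs)))
    matrix(out, nrow = length(labs), dimnames = list(labs, NULL))
  }
  counts <- count_matrix(lapply(runs, function(r) r$labels))
  cv <- apply(counts, 1, count_cv)
  layer_cv <- vapply(list(
    lapply(runs, function(r) r$layer1),
    lapply(runs, function(r) r$layer2[!is.na(r$layer2)]),
    lapply(runs, function(r) r$labels)
  ), function(ll) mean(apply(count_matrix(ll), 1, count_cv), na.rm = TRUE), numeric(1))
  list(counts = counts, cv = cv, mean_cv = mean(cv, na.rm = TRUE),
       layer_mean_cv = stats::setNames(layer_cv, c("layer1", "layer2", "layer3")))
}
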