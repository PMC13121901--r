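## Synthetic study generator: lognormal fluorescence peaks on a lognormal
## autofluorescence floor, five single-stain bead controls plus an unlabeled
## cell control per acquisition day, and labeled cell samples whose
## population mixture depends on passage. The per-channel affine batch
## effect is applied to one day only, emulating a day-to-day acquisition
## shift the normalization module has to remove.

#' Population specification
#'
#' @param name population name.
#' @param location named positive vector: per-channel linear-scale lognormal
#'   median.
#' @param spread named positive vector (or scalar): per-channel lognormal
#'   sigma.
#' @param proportion_by_passage named vector mapping passage number (as
#'   name) to the population's fraction of labeled cells at that passage.
#' @return a `population_spec` object.
#' @export
population_spec <- function(name, location, spread, proportion_by_passage) {
  if (any(location <= 0) || any(spread <= 0))
    cc_stop("locations and spreads must be positive", "cc_design_error")
  if (length(spread) == 1) spread <- stats::setNames(rep(spread, length(location)), names(location))
  structure(list(name = name, location = location, spread = spread,
                 proportion_by_passage = proportion_by_passage),
            class = "population_spec")
}

#' Batch effect specification
#'
#' Affine per-channel acquisition distortion applied to every sample of one
#' day: `value * gain + offset`.
#'
#' @param channel channel name.
#' @param gain positive multiplier.
#' @param offset additive shift (linear scale).
#' @param day day the effect applies to.
#' @return a `batch_effect` object.
#' @export
batch_effect <- function(channel, gain = 1, offset = 0, day) {
  if (gain <= 0) cc_stop("batch effect gain must be positive", "cc_design_error")
  structure(list(channel = channel, gain = gain, offset = offset, day = as.integer(day)),
            class = "batch_effect")
}

#' Study design
#'
#' Everything needed to simulate a study: the panel, the labeled-cell
#' populations, bead peak and cell autofluorescence parameters, per-sample
#' event counts, batch effects and the day-to-passage map.
#'
#' @param panel a [channel_panel()].
#' @param populations list of [population_spec()].
#' @param bead_positive_location,bead_positive_spread lognormal parameters
#'   of the positive bead peak (scalar or per channel).
#' @param bead_negative_location,bead_negative_spread parameters of the
#'   negative bead peak.
#' @param autofluor_location,autofluor_spread parameters of the cell
#'   autofluorescence floor.
#' @param events_per_cell_sample,events_per_bead_sample event counts.
#' @param batch_effects list of [batch_effect()].
#' @param passage_by_day named vector mapping day (as name) to passage.
#' @param bead_positive_fraction fraction of positive beads in a bead
#'   sample.
#' @param cell_day_drift named list mapping day (as name) to a per-channel
#'   multiplier applied to CELL samples of that day (unlabeled and
#'   labeled): the biological drift of the cultured line between
#'   acquisition days. Beads are synthetic particles and are not affected,
#'   which is exactly why they can anchor the instrumental normalization
#'   while this drift remains -- the variation the control-adjusted T(x)
#'   subtracts.
#' @return a `study_design` object.
#' @export
study_design <- function(panel, populations,
                         bead_positive_location = 12000, bead_positive_spread = 0.18,
                         bead_negative_location = 20, bead_negative_spread = 0.15,
                         autofluor_location = 150, autofluor_spread = 0.5,
                         events_per_cell_sample = 20000,
                         events_per_bead_sample = 5000,
                         batch_effects = list(),
                         passage_by_day = c("1" = 5, "2" = 12),
                         bead_positive_fraction = 0.5,
                         cell_day_drift = list()) {
  ch <- panel$channels
  per_channel <- function(x, what) {
    if (length(x) == 1) return(stats::setNames(rep(x, length(ch)), ch))
    if (is.null(names(x)) || !all(ch %in% names(x)))
      cc_stop(paste0(what, " must be scalar or named per panel channel"), "cc_design_error")
    x[ch]
  }
  for (p in populations) {
    if (!all(names(p$location) %in% ch) || !all(ch %in% names(p$location)))
      cc_stop(paste0("population ", p$name, " references channels outside the panel"),
              "cc_spec_error")
  }
  for (b in batch_effects) {
    if (!b$channel %in% ch)
      cc_stop(paste0("batch effect references unknown channel ", b$channel), "cc_spec_error")
  }
  for (d in names(passage_by_day)) {
    tot <- sum(vapply(populations, function(p) {
      pr <- p$proportion_by_passage[as.character(passage_by_day[[d]])]
      if (is.na(pr)) 0 else pr
    }, numeric(1)))
    if (abs(tot - 1) > 1e-9)
      cc_stop(sprintf("population proportions for passage %s sum to %.6f, not 1",
                      passage_by_day[[d]], tot), "cc_design_error")
  }
  structure(list(
    panel = panel, populations = populations,
    bead_positive_location = per_channel(bead_positive_location, "bead_positive_location"),
    bead_positive_spread = per_channel(bead_positive_spread, "bead_positive_spread"),
    bead_negative_location = per_channel(bead_negative_location, "bead_negative_location"),
    bead_negative_spread = per_channel(bead_negative_spread, "bead_negative_spread"),
    autofluor_location = per_channel(autofluor_location, "autofluor_location"),
    autofluor_spread = per_channel(autofluor_spread, "autofluor_spread"),
    events_per_cell_sample = events_per_cell_sample,
    events_per_bead_sample = events_per_bead_sample,
    batch_effects = batch_effects, passage_by_day = passage_by_day,
    bead_positive_fraction = bead_positive_fraction,
    cell_day_drift = lapply(cell_day_drift, function(x) per_channel(x, "cell_day_drift"))
  ), class = "study_design")
}

apply_batch_effects <- function(values, design, day) {
  for (b in design$batch_effects) {
    j <- match(b$channel, design$panel$channels)
    if (b$day == day) values[, j] <- values[, j] * b$gain + b$offset
  }
  values
}

## biological drift of the cell line, per day (cells only, never beads)
apply_cell_drift <- function(values, design, day) {
  dr <- design$cell_day_drift[[as.character(day)]]
  if (is.null(dr)) return(values)
  sweep(values, 2, dr[design$panel$channels], "*")
}

#' Draw events from one population
#'
#' Each channel is lognormal around the population's location with its
#' spread, plus an independent lognormal autofluorescence floor.
#'
#' @param p a [population_spec()].
#' @param n number of events.
#' @param seed integer seed.
#' @param panel a [channel_panel()]; defaults to the channels named in the
#'   population's location.
#' @param autofluor_location,autofluor_spread autofluorescence floor
#'   parameters (scalar or named per channel); `NULL` for no floor.
#' @param passage unused by the draw itself (mixture weights act at the
#'   study level); kept for bookkeeping.
#' @return an [event_matrix()] on the linear scale.
#' @export
sample_population <- function(p, n, seed, panel = NULL,
                              autofluor_location = NULL, autofluor_spread = NULL,
                              passage = NULL) {
  if (is.null(panel)) panel <- channel_panel(names(p$location))
  ch <- panel$channels
  if (!all(ch %in% names(p$location)))
    cc_stop("population does not cover all panel channels", "cc_spec_error")
  if (n == 0) return(event_matrix(matrix(numeric(0), 0, length(ch)), panel))
  af <- !is.null(autofluor_location)
  if (af && length(autofluor_location) == 1)
    autofluor_location <- stats::setNames(rep(autofluor_location, length(ch)), ch)
  if (af && length(autofluor_spread) == 1)
    autofluor_spread <- stats::setNames(rep(autofluor_spread, length(ch)), ch)
  v <- with_seed(seed, {
    out <- matrix(0, n, length(ch))
    for (j in seq_along(ch)) {
      c_ <- ch[j]
      out[, j] <- stats::rlnorm(n, log(p$location[[c_]]), p$spread[[c_]])
      if (af) out[, j] <- out[, j] +
          stats::rlnorm(n, log(autofluor_location[[c_]]), autofluor_spread[[c_]])
    }
    out
  })
  event_matrix(v, panel)
}

#' Generate one single-stain bead control sample
#'
#' Mixture of sharp negative and positive lognormal peaks on the stained
#' channel, negative peak on all others; the day's batch effects are
#' applied.
#'
#' @param d a [study_design()].
#' @param channel stained channel.
#' @param day acquisition day.
#' @param n number of events (defaults to the design's bead sample size).
#' @param seed integer seed.
#' @return `list(meta, events, truth)` where truth is `"neg_bead"` /
#'   `"pos_bead"` per event.
#' @export
generate_bead_sample <- function(d, channel, day, n = d$events_per_bead_sample, seed) {
  if (!channel %in% d$panel$channels)
    cc_stop(paste0("unknown stain channel ", channel), "cc_spec_error")
  ch <- d$panel$channels
  n_pos <- round(n * d$bead_positive_fraction)
  v <- with_seed(seed, {
    out <- matrix(0, n, length(ch))
    for (j in seq_along(ch)) {
      c_ <- ch[j]
      out[, j] <- stats::rlnorm(n, log(d$bead_negative_location[[c_]]),
                                d$bead_negative_spread[[c_]])
      if (c_ == channel && n_pos > 0) {
        out[seq_len(n_pos), j] <- stats::rlnorm(n_pos, log(d$bead_positive_location[[c_]]),
                                                d$bead_positive_spread[[c_]])
      }
    }
    out
  })
  v <- apply_batch_effects(v, d, day)
  list(meta = sample_meta(sprintf("beads_%s_day%d", channel, day),
                          "bead_single_stain", channel, day),
       events = event_matrix(v, d$panel),
       truth = c(rep("pos_bead", n_pos), rep("neg_bead", n - n_pos)))
}

#' Generate a complete synthetic study
#'
#' Per acquisition day: one single-stain bead control per channel, one
#' unlabeled cell sample (autofluorescence only) and one labeled cell sample
#' whose population mixture follows the design's proportions for that day's
#' passage (counts drawn multinomially). Batch effects apply to their day's
#' samples only. With the reference two-day design this yields 14 samples,
#' 7 per day.
#'
#' @param d a [study_design()].
#' @param seed integer seed; all per-sample seeds derive from it.
#' @return a [study_set()]; each sample also carries a `truth` vector of
#'   generating population names.
#' @export
generate_study <- function(d, seed) {
  days <- as.integer(names(d$passage_by_day))
  ch <- d$panel$channels
  n_per_day <- length(ch) + 2L
  seeds <- derive_seeds(seed, length(days) * n_per_day)
  samples <- list()
  si <- 0L
  for (day in days) {
    passage <- d$passage_by_day[[as.character(day)]]
    for (c_ in ch) {
      si <- si + 1L
      samples[[length(samples) + 1]] <-
        generate_bead_sample(d, c_, day, seed = seeds[si])
    }
    ## unlabeled cells: autofluorescence only
    si <- si + 1L
    n <- d$events_per_cell_sample
    v <- with_seed(seeds[si], {
      out <- matrix(0, n, length(ch))
      for (j in seq_along(ch))
        out[, j] <- stats::rlnorm(n, log(d$autofluor_location[[ch[j]]]),
                                  d$autofluor_spread[[ch[j]]])
      out
    })
    v <- apply_batch_effects(apply_cell_drift(v, d, day), d, day)
    samples[[length(samples) + 1]] <- list(
      meta = sample_meta(sprintf("unlabeled_day%d", day), "unlabeled_cells", day = day),
      events = event_matrix(v, d$panel),
      truth = rep("unlabeled", n))
    ## labeled cells: multinomial mixture of populations at this passage
    si <- si + 1L
    props <- vapply(d$populations, function(p) {
      pr <- p$proportion_by_passage[as.character(passage)]
      if (is.na(pr)) 0 else unname(pr)
    }, numeric(1))
    sub <- derive_seeds(seeds[si], length(d$populations) + 1L)
    counts <- with_seed(sub[1], as.integer(stats::rmultinom(1, n, props)))
    parts <- vector("list", length(d$populations))
    for (k in seq_along(d$populations)) {
      parts[[k]] <- sample_population(
        d$populations[[k]], counts[k], sub[k + 1L], panel = d$panel,
        autofluor_location = d$autofluor_location,
        autofluor_spread = d$autofluor_spread)$values
    }
    v <- apply_batch_effects(apply_cell_drift(do.call(rbind, parts), d, day), d, day)
    truth <- rep(vapply(d$populations, function(p) p$name, character(1)), counts)
    samples[[length(samples) + 1]] <- list(
      meta = sample_meta(sprintf("labeled_P%d_day%d", passage, day),
                         "labeled_cells", day = day, passage = passage),
      events = event_matrix(v, d$panel),
      truth = truth)
  }
  study_set(samples)
}

#' Reference synthetic study design
#'
#' The default study conditions: the five-marker stromal panel; four
#' labeled-cell populations (hematopoietic, lymphatic-endothelial-like,
#' perivascular-like, fibroblastic-reticular-like) at the published passage
#' 5 / passage 12 proportions, optionally with a small ICAM1-raised
#' "MRC-like" subpopulation carved out of the reticular population; sharp
#' bead peaks; and a strong day-2 ICAM1 gain distortion.
#'
#' @param n_cells events per cell sample.
#' @param n_beads events per bead sample.
#' @param separation `"well_separated"` (sigma 0.35) or `"overlapping"`
#'   (sigma 0.85, positive signal pulled down towards the autofluorescence
#'   floor so neighbouring populations overlap heavily).
#' @param mrc_fraction fraction of the reticular population reassigned to
#'   the MRC-like subpopulation (0 disables it).
#' @param batch_gain,batch_offset,batch_channel day-2 batch distortion;
#'   `batch_gain = 1, batch_offset = 0` disables it.
#' @return a [study_design()].
#' @export
reference_design <- function(n_cells = 20000, n_beads = 5000,
                             separation = c("well_separated", "overlapping"),
                             mrc_fraction = 0,
                             batch_gain = 0.4, batch_offset = 15,
                             batch_channel = "ICAM1") {
  separation <- match.arg(separation)
  panel <- reference_panel()
  sigma <- if (separation == "well_separated") 0.35 else 0.85
  shrink <- if (separation == "well_separated") 1 else 0.35
  pos <- function(x) ifelse(x >= 1000, x * shrink, x)
  loc <- function(...) {
    v <- c(...)
    stats::setNames(pos(v), panel$channels)
  }
  p5 <- c(hematopoietic = 0.0781, LEC = 0.0544, PvC = 0.0041, FRC = 0.8634)
  p12 <- c(hematopoietic = 0.0001, LEC = 0.0027, PvC = 0.0584, FRC = 0.9388)
  p5 <- p5 / sum(p5); p12 <- p12 / sum(p12)
  prop <- function(name) c("5" = unname(p5[name]), "12" = unname(p12[name]))
  pops <- list(
    population_spec("hematopoietic", loc(9000, 2500, 1800, 5000, 3000), sigma,
                    prop("hematopoietic")),
    population_spec("LEC", loc(30, 7000, 5000, 3500, 2500), sigma, prop("LEC")),
    population_spec("PvC", loc(25, 30, 40, 35, 4500), sigma, prop("PvC")),
    population_spec("FRC", loc(28, 35, 4200, 40, 3800), sigma, prop("FRC"))
  )
  if (mrc_fraction > 0) {
    frc <- pops[[4]]
    pops[[4]] <- population_spec("FRC", frc$location, frc$spread,
                                 frc$proportion_by_passage * (1 - mrc_fraction))
    mrc_loc <- frc$location
    mrc_loc["ICAM1"] <- pos(2500)
    pops[[5]] <- population_spec("MRC", mrc_loc, frc$spread,
                                 frc$proportion_by_passage * mrc_fraction)
  }
  be <- if (batch_gain != 1 || batch_offset != 0)
    list(batch_effect(batch_channel, batch_gain, batch_offset, day = 2L)) else list()
  ## modest biological drift of the line between the two acquisition days
  ## (the passage-5 vs passage-12 shift the unlabeled control registers)
  drift <- list("2" = c(CD45 = 0.90, CD31 = 1.15, PDPN = 1.10,
                        ICAM1 = 1.25, VCAM1 = 0.85))
  study_design(panel, pops,
               events_per_cell_sample = n_cells, events_per_bead_sample = n_beads,
               batch_effects = be, cell_day_drift = drift)
}

#' Write a study to a directory of CSV files
#'
#' One CSV per sample plus a `metadata.csv` table (and `truth_*.csv`
#' generating-population labels when present).
#'
#' @param study a [study_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- do.call(rbind, lapply(study$samples, function(s) {
    data.frame(sample_id = s$meta$sample_id, sample_type = s$meta$sample_type,
               stain_channel = s$meta$stain_channel, day = s$meta$day,
               passage = s$meta$passage, file = paste0(s$meta$sample_id, ".csv"))
  }))
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (s in study$samples) {
    write_events_csv(s$events, file.path(dir, paste0(s$meta$sample_id, ".csv")))
    if (!is.null(s$truth))
      utils::write.csv(data.frame(truth = s$truth),
                       file.path(dir, paste0("truth_", s$meta$sample_id, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing `metadata.csv` and per-sample CSVs.
#' @return a [study_set()].
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "metadata.csv")
  if (!file.exists(mpath))
    cc_stop(paste0("no metadata.csv in ", dir), "cc_format_error")
  md <- utils::read.csv(mpath)
  samples <- lapply(seq_len(nrow(md)), function(i) {
    meta <- sample_meta(md$sample_id[i], md$sample_type[i],
                        if (is.na(md$stain_channel[i])) NA_character_ else md$stain_channel[i],
                        md$day[i],
                        if (is.na(md$passage[i])) NA_integer_ else md$passage[i])
    ev <- read_events(file.path(dir, md$file[i]))
    tpath <- file.path(dir, paste0("truth_", md$sample_id[i], ".csv"))
    truth <- if (file.exists(tpath)) utils::read.csv(tpath)$truth else NULL
    list(meta = meta, events = ev, truth = truth)
  })
  study_set(samples)
}
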