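## Two-point bead-anchored batch normalization. Single-stain compensation
## beads give each channel two sharp anchor peaks per day (negative and
## positive); assuming the number of bound antibodies is identical across
## days, intensities on the two days are related by the affine map through
## the two anchor pairs:
##
##   I_ref = (I_ref_high - I_ref_low) / (I_day_high - I_day_low) *
##           (I_day - I_day_low) + I_ref_low
##
## The slope ratio acts as a multiplier: when it exceeds 1 the normalized
## day's spread is amplified (worst at low signal), so it is reported per
## channel.

#' Control peak pair
#'
#' Summary statistics (median or mean) of the negative and positive control
#' peaks of one channel on one day.
#'
#' @param low lower-peak statistic (linear scale).
#' @param high higher-peak statistic.
#' @param statistic `"median"` or `"mean"`.
#' @return a `peak_pair` object.
#' @export
peak_pair <- function(low, high, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!is.finite(low) || !is.finite(high) || high <= low)
    cc_stop("peak pair requires high > low", "cc_parameter_error")
  structure(list(low = low, high = high, statistic = statistic), class = "peak_pair")
}

#' Detect the two control peaks of a bead channel
#'
#' Kernel-density estimate (Silverman bandwidth) on the arcsinh scale; the
#' two highest-density modes are located, events are split at the deepest
#' density valley between them, and the chosen statistic of each side is
#' returned on the linear scale.
#'
#' @param values linear-scale intensities of one channel of a bead sample
#'   (at least 200 events).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param cofactor arcsinh cofactor for the density estimate.
#' @param min_separation minimum distance between the two modes on the
#'   arcsinh scale; closer modes raise an ambiguous-peaks error.
#' @return a [peak_pair()].
#' @export
detect_control_peaks <- function(values, statistic = c("median", "mean"),
                                 cofactor = 150, min_separation = 0.5) {
  statistic <- match.arg(statistic)
  if (length(values) < 200)
    cc_stop("peak detection requires at least 200 events", "cc_parameter_error")
  y <- asinh(values / cofactor)
  d <- stats::density(y, bw = "nrd0")
  k <- length(d$y)
  is_max <- c(d$y[1] > d$y[2],
              d$y[2:(k - 1)] > d$y[1:(k - 2)] & d$y[2:(k - 1)] >= d$y[3:k],
              d$y[k] > d$y[k - 1])
  modes <- which(is_max)
  modes <- modes[d$y[modes] >= 0.05 * max(d$y)]  # ignore negligible wiggles
  if (length(modes) < 2)
    cc_stop("control distribution is unimodal: no peak pair to anchor",
            "cc_unimodal_error")
  top2 <- modes[order(d$y[modes], decreasing = TRUE)[1:2]]
  lo_i <- min(top2); hi_i <- max(top2)
  valley_i <- lo_i + which.min(d$y[lo_i:hi_i]) - 1L
  ## bimodality requires a genuine valley between the two candidate modes
  if (d$y[valley_i] > 0.8 * min(d$y[top2]))
    cc_stop("control distribution is unimodal: no peak pair to anchor",
            "cc_unimodal_error")
  if (abs(d$x[top2[1]] - d$x[top2[2]]) < min_separation)
    cc_stop("the two dominant modes are too close to separate reliably",
            "cc_ambiguous_peaks_error")
  thr <- sinh(d$x[valley_i]) * cofactor
  lower <- values[values <= thr]
  upper <- values[values > thr]
  stat <- if (statistic == "median") stats::median else mean
  peak_pair(stat(lower), stat(upper), statistic)
}

#' Fit the two-point normalization model
#'
#' The affine map sending the second day's anchors exactly onto the first
#' (reference) day's anchors.
#'
#' @param day1 reference-day [peak_pair()].
#' @param day2 [peak_pair()] of the day to be normalized.
#' @param channel channel name.
#' @return a `two_point_norm` model with `slope_ratio`
#'   `(day1$high - day1$low) / (day2$high - day2$low)`.
#' @export
fit_two_point_norm <- function(day1, day2, channel = NA_character_) {
  denom <- day2$high - day2$low
  if (denom == 0)
    cc_stop("degenerate control: day-2 peaks coincide", "cc_degenerate_control_error")
  structure(list(day1 = day1, day2 = day2,
                 slope_ratio = (day1$high - day1$low) / denom,
                 channel = channel, identity = FALSE),
            class = "two_point_norm")
}

#' Identity normalization model
#'
#' Used for channels whose anchors already agree within tolerance, so no
#' noise-amplifying correction is applied.
#'
#' @param channel channel name.
#' @return a `two_point_norm` mapping every value to itself.
#' @export
identity_norm <- function(channel = NA_character_) {
  structure(list(day1 = peak_pair(0, 1), day2 = peak_pair(0, 1),
                 slope_ratio = 1, channel = channel, identity = TRUE),
            class = "two_point_norm")
}

#' Apply a two-point normalization model
#'
#' @param m a `two_point_norm` model.
#' @param values linear-scale intensities of the model's channel, measured
#'   on the day being normalized.
#' @return normalized intensities; the two anchors map exactly onto the
#'   reference anchors and ordering is preserved.
#' @export
apply_norm <- function(m, values) {
  m$slope_ratio * (values - m$day2$low) + m$day1$low
}

#' @export
print.two_point_norm <- function(x, ...) {
  if (x$identity) {
    cat(sprintf("<two_point_norm> %s: identity (no detectable batch effect)\n", x$channel))
  } else {
    cat(sprintf("<two_point_norm> %s: slope_ratio %.4f, anchors (%.1f, %.1f) -> (%.1f, %.1f)\n",
                x$channel, x$slope_ratio, x$day2$low, x$day2$high, x$day1$low, x$day1$high))
  }
  invisible(x)
}

#' Normalize a two-day study against its bead controls
#'
#' Per channel, control peaks are detected in that channel's single-stain
#' bead sample on each day. If the anchors differ by less than `tol`
#' (relative), the channel keeps the identity model; otherwise the
#' lower-signal day (smaller positive-peak anchor) is mapped onto the
#' higher-signal day and the model is applied to every sample of the
#' normalized day, bead controls included.
#'
#' @param study a [study_set()] with exactly two acquisition days and one
#'   single-stain bead sample per channel per day.
#' @param statistic peak statistic, `"median"` (default) or `"mean"`.
#' @param tol relative anchor-difference below which a channel is left
#'   untouched.
#' @param cofactor arcsinh cofactor for peak detection.
#' @return `list(study, report, models)`: the normalized study, a
#'   per-channel data frame of anchors and `slope_ratio` (the amplification
#'   caveat: slope_ratio > 1 widens the normalized day's spread), and the
#'   fitted models.
#' @export
normalize_study <- function(study, statistic = c("median", "mean"),
                            tol = 0.01, cofactor = 150) {
  statistic <- match.arg(statistic)
  days <- study_days(study)
  if (length(days) != 2)
    cc_stop("bead normalization requires exactly two acquisition days",
            "cc_parameter_error")
  ch <- channels(study)
  models <- list()
  rows <- list()
  for (c_ in ch) {
    pairs <- lapply(days, function(d) {
      bs <- study_samples(study, "bead_single_stain", day = d, stain_channel = c_)
      if (length(bs) != 1)
        cc_stop(sprintf("expected one %s bead sample on day %d", c_, d),
                "cc_parameter_error")
      detect_control_peaks(bs[[1]]$events$values[, c_], statistic, cofactor)
    })
    rel <- max(abs(pairs[[1]]$high - pairs[[2]]$high) /
                 max(abs(pairs[[1]]$high), abs(pairs[[2]]$high)),
               abs(pairs[[1]]$low - pairs[[2]]$low) /
                 max(abs(pairs[[1]]$low), abs(pairs[[2]]$low), 1e-12))
    if (rel < tol) {
      models[[c_]] <- identity_norm(c_)
      rows[[c_]] <- data.frame(channel = c_, reference_day = NA_integer_,
                               normalized_day = NA_integer_, slope_ratio = 1,
                               anchor_rel_diff = rel, identity = TRUE)
    } else {
      ref <- if (pairs[[1]]$high >= pairs[[2]]$high) 1L else 2L
      mov <- 3L - ref
      m <- fit_two_point_norm(pairs[[ref]], pairs[[mov]], c_)
      m$normalized_day <- days[mov]
      m$reference_day <- days[ref]
      models[[c_]] <- m
      rows[[c_]] <- data.frame(channel = c_, reference_day = days[ref],
                               normalized_day = days[mov], slope_ratio = m$slope_ratio,
                               anchor_rel_diff = rel, identity = FALSE)
    }
  }
  samples <- lapply(study$samples, function(s) {
    for (c_ in ch) {
      m <- models[[c_]]
      if (!m$identity && s$meta$day == m$normalized_day)
        s$events$values[, c_] <- apply_norm(m, s$events$values[, c_])
    }
    s
  })
  list(study = study_set(samples), report = do.call(rbind, rows), models = models)
}
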