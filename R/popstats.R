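## Probability-binning chi-squared comparison. Bins are defined on the
## CONTROL sample so that each holds (as nearly as possible) the same
## number of control events -- univariate via quantile edges, multivariate
## via a recursive median-split tree. The test sample's occupancy is
## compared by the two-sample chi-squared statistic, standardized against
## the chi-squared reference (mean B-1, SD sqrt(2(B-1))) and floored at
## zero: T(x) ~ 0 means indistinguishable from the control, large values
## mean distinct. Because the bins are fitted to the control itself, the
## null statistic sits well below B-1, making the floored score
## conservative by construction. The bin count never exceeds 10% of the
## smaller sample.

#' Probability-binning scheme from a control sample
#'
#' `B = min(B_requested, floor(n_control / 10))`. Univariate schemes place
#' edges between control order statistics for equal occupancy;
#' multivariate schemes recursively split the most-populated bin at the
#' median of its highest-variance channel.
#'
#' @param control numeric vector (univariate), or matrix /
#'   [event_matrix()] (multivariate).
#' @param B_requested requested number of bins.
#' @return a `binning_scheme` with fields `type`, `B`, `n_control` and the
#'   edge vector or split tree.
#' @export
probability_bins <- function(control, B_requested) {
  uni <- is.numeric(control) && is.null(dim(control))
  X <- if (uni) control else event_values(control)
  n <- if (uni) length(X) else nrow(X)
  B <- as.integer(min(B_requested, floor(n / 10)))
  if (B < 2)
    cc_stop("too few control events for at least 2 bins", "cc_parameter_error")
  if (uni) {
    s <- sort(X)
    ## edges sit ON control order statistics (bin k holds values <= edge k),
    ## so any strictly monotone transform applied to control and test alike
    ## leaves the occupancies -- and hence T(x) -- exactly unchanged
    edges <- s[round(n * seq_len(B - 1) / B)]
    scheme <- list(type = "univariate", B = B, n_control = n, edges = edges)
  } else {
    ## iterative median-split tree; nodes as a growing table
    nodes <- list(list(leaf = TRUE, idx = seq_len(n)))
    while (sum(vapply(nodes, function(nd) nd$leaf, logical(1))) < B) {
      leaves <- which(vapply(nodes, function(nd) nd$leaf, logical(1)))
      sizes <- vapply(leaves, function(i) length(nodes[[i]]$idx), integer(1))
      cand <- leaves[order(-sizes)]
      split_done <- FALSE
      for (li in cand) {
        idx <- nodes[[li]]$idx
        if (length(idx) < 2) next
        vr <- matrixStats::colVars(X[idx, , drop = FALSE])
        if (all(vr <= 0)) next
        j <- which.max(vr)
        cutoff <- stats::median(X[idx, j])
        left <- idx[X[idx, j] <= cutoff]
        right <- idx[X[idx, j] > cutoff]
        if (length(left) == 0 || length(right) == 0) {
          ## all mass at the median; split strictly below
          left <- idx[X[idx, j] < cutoff]
          right <- idx[X[idx, j] >= cutoff]
          if (length(left) == 0 || length(right) == 0) next
          cutoff <- max(X[idx, j][X[idx, j] < cutoff])
        }
        nodes[[li]] <- list(leaf = FALSE, channel = j, cutoff = cutoff,
                            left = length(nodes) + 1L, right = length(nodes) + 2L)
        nodes[[length(nodes) + 1L]] <- list(leaf = TRUE, idx = left)
        nodes[[length(nodes) + 1L]] <- list(leaf = TRUE, idx = right)
        split_done <- TRUE
        break
      }
      if (!split_done) break  # nothing splittable; accept fewer bins
    }
    leaf_ids <- which(vapply(nodes, function(nd) nd$leaf, logical(1)))
    leaf_no <- integer(length(nodes))
    leaf_no[leaf_ids] <- seq_along(leaf_ids)
    nodes <- lapply(nodes, function(nd) { nd$idx <- NULL; nd })
    scheme <- list(type = "multivariate", B = as.integer(length(leaf_ids)), n_control = n,
                   tree = nodes, leaf_no = leaf_no,
                   channels = colnames(X) %||% seq_len(ncol(X)))
  }
  structure(scheme, class = "binning_scheme")
}

#' Assign events to probability bins
#'
#' @param scheme a [probability_bins()] scheme.
#' @param values numeric vector or matrix matching the scheme's
#'   dimensionality.
#' @return integer bin id in `1..B` per event.
#' @export
bin_assign <- function(scheme, values) {
  if (scheme$type == "univariate") {
    return(findInterval(values, scheme$edges, left.open = TRUE) + 1L)
  }
  X <- event_values(values)
  node <- rep(1L, nrow(X))
  repeat {
    active <- which(!vapply(scheme$tree[node], function(nd) nd$leaf, logical(1)))
    if (length(active) == 0) break
    nd_ids <- node[active]
    for (u in unique(nd_ids)) {
      nd <- scheme$tree[[u]]
      rows <- active[nd_ids == u]
      go_left <- X[rows, nd$channel] <= nd$cutoff
      node[rows[go_left]] <- nd$left
      node[rows[!go_left]] <- nd$right
    }
  }
  scheme$leaf_no[node]
}

#' Probability-binning chi-squared T(x) score
#'
#' Two-sample chi-squared over the scheme's bins, standardized against the
#' reference distribution (`mu0 = B - 1`, `sd0 = sqrt(2(B-1))`, or
#' seeded Monte-Carlo moments at the observed sizes), with a guard band of
#' `guard` null standard deviations and floored at zero:
#' `tx = max(0, (chi2 - mu0)/sd0 - guard)`. Within-band scores report 0 --
#' indistinguishable from the control -- so the null expectation of the
#' floored score is ~0 rather than the ~0.4 a plain floored z-score has
#' (consistent with how often published control comparisons print exact
#' zeros).
#'
#' @param bins a [probability_bins()] scheme (built from `control`).
#' @param control,test samples on the scheme's space.
#' @param null `"analytic"` (default) or `"montecarlo"`.
#' @param guard guard band in null standard deviations (default 1; 0 gives
#'   the plain floored z-score).
#' @param mc_reps,seed Monte-Carlo settings.
#' @return a `tx_result`: `chi2`, `B`, `n_control`, `n_test`, `tx`,
#'   `null_mean`, `null_sd`.
#' @export
tx_score <- function(bins, control, test, null = c("analytic", "montecarlo"),
                     guard = 1, mc_reps = 500, seed = 1) {
  null <- match.arg(null)
  nc <- if (is.null(dim(control))) length(control) else nrow(event_values(control))
  nt <- if (is.null(dim(test))) length(test) else nrow(event_values(test))
  if (nt == 0) cc_stop("empty test sample", "cc_parameter_error")
  if (bins$B > floor(min(nc, nt) / 10))
    cc_stop(sprintf(
      "bin count %d exceeds 10%% of the smaller sample (n = %d); rebuild with fewer bins",
      bins$B, min(nc, nt)), "cc_parameter_error")
  cb <- tabulate(bin_assign(bins, control), bins$B)
  tb <- tabulate(bin_assign(bins, test), bins$B)
  chi2 <- chi2_two_sample(cb, tb)
  if (null == "analytic") {
    mu0 <- bins$B - 1
    sd0 <- sqrt(2 * (bins$B - 1))
  } else {
    sims <- with_seed(seed, vapply(seq_len(mc_reps), function(r) {
      chi2_two_sample(as.integer(stats::rmultinom(1, nc, rep(1, bins$B))),
                      as.integer(stats::rmultinom(1, nt, rep(1, bins$B))))
    }, numeric(1)))
    mu0 <- mean(sims); sd0 <- stats::sd(sims)
  }
  structure(list(chi2 = chi2, B = bins$B, n_control = nc, n_test = nt,
                 tx = max(0, (chi2 - mu0) / sd0 - guard),
                 null_mean = mu0, null_sd = sd0, null = null, guard = guard),
            class = "tx_result")
}

chi2_two_sample <- function(cb, tb) {
  nc <- sum(cb); nt <- sum(tb)
  tot <- cb + tb
  keep <- tot > 0
  p <- tot[keep] / (nc + nt)
  ec <- nc * p; et <- nt * p
  sum((cb[keep] - ec)^2 / ec + (tb[keep] - et)^2 / et)
}

#' @export
print.tx_result <- function(x, ...) {
  cat(sprintf("<tx_result> T(x) = %.4f (chi2 %.1f, B %d, n %d vs %d)\n",
              x$tx, x$chi2, x$B, x$n_control, x$n_test))
  invisible(x)
}

#' One-call probability-binning comparison
#'
#' Builds the binning from the control with the bin cap applied to BOTH
#' sample sizes, then scores the test sample.
#'
#' @param control,test numeric vectors or matrices.
#' @param B_requested requested bins before the 10% cap.
#' @param ... passed to [tx_score()].
#' @return a `tx_result`.
#' @export
tx_compare <- function(control, test, B_requested = 100, ...) {
  nc <- if (is.null(dim(control))) length(control) else nrow(event_values(control))
  nt <- if (is.null(dim(test))) length(test) else nrow(event_values(test))
  B <- min(B_requested, floor(min(nc, nt) / 10))
  bins <- probability_bins(control, B)
  tx_score(bins, control, test, ...)
}

#' Day-to-day control variability per channel
#'
#' For every channel, each control population (the positive beads of each
#' single-stain sample, the pooled negative beads, and the unlabeled
#' cells) is compared between the two acquisition days with the univariate
#' T(x). The channel's variability level is the maximum over control
#' comparisons, EXCLUDING any control whose T(x) exceeds the
#' unlabeled-cells T(x) on that channel (such a control reflects
#' transform-amplified spread rather than biological variability, the
#' rationale for dropping the inflated negative-bead comparison).
#'
#' @param study a two-day [study_set()] (normalized, if normalization is in
#'   use).
#' @param B_requested requested bins per comparison.
#' @param cofactor arcsinh cofactor for the bead positive/negative split.
#' @return list with `variability` (named per channel), the full
#'   control-by-channel `table` and the `excluded` flags.
#' @export
control_variability <- function(study, B_requested = 100, cofactor = 150) {
  days <- study_days(study)
  if (length(days) != 2)
    cc_stop("control variability requires both days' controls", "cc_parameter_error")
  ch <- channels(study)
  ## split each bead sample into negative / positive at the stained
  ## channel's density valley
  split_bead <- function(s) {
    v <- s$events$values
    stained <- s$meta$stain_channel
    pp <- detect_control_peaks(v[, stained], cofactor = cofactor)
    thr_mid <- (asinh(pp$low / cofactor) + asinh(pp$high / cofactor)) / 2
    pos <- asinh(v[, stained] / cofactor) > thr_mid
    list(pos = v[pos, , drop = FALSE], neg = v[!pos, , drop = FALSE])
  }
  pools <- list()
  for (d in days) {
    dd <- as.character(d)
    negs <- list()
    for (s in study_samples(study, "bead_single_stain", day = d)) {
      sp <- split_bead(s)
      pools[[paste0("bead_", s$meta$stain_channel)]][[dd]] <- sp$pos
      negs[[length(negs) + 1]] <- sp$neg
    }
    pools[["negative_beads"]][[dd]] <- do.call(rbind, negs)
    unl <- study_samples(study, "unlabeled_cells", day = d)
    pools[["unlabeled_cells"]][[dd]] <-
      do.call(rbind, lapply(unl, function(s) s$events$values))
  }
  if (is.null(pools[["unlabeled_cells"]][[as.character(days[1])]]))
    cc_stop("no unlabeled controls present", "cc_parameter_error")
  ctrls <- names(pools)
  tab <- matrix(NA_real_, length(ctrls), length(ch), dimnames = list(ctrls, ch))
  for (cn in ctrls) {
    x1 <- pools[[cn]][[as.character(days[1])]]
    x2 <- pools[[cn]][[as.character(days[2])]]
    for (c_ in ch) tab[cn, c_] <- tx_compare(x1[, c_], x2[, c_], B_requested)$tx
  }
  excluded <- matrix(FALSE, length(ctrls), length(ch), dimnames = dimnames(tab))
  varlev <- stats::setNames(numeric(length(ch)), ch)
  for (c_ in ch) {
    ref <- tab["unlabeled_cells", c_]
    excluded[, c_] <- rownames(tab) != "unlabeled_cells" & tab[, c_] > ref
    varlev[c_] <- max(tab[!excluded[, c_], c_])
  }
  list(variability = varlev, table = tab, excluded = excluded)
}

#' Control-adjusted per-channel T(x) of a population
#'
#' Compares the population against the unlabeled reference channel by
#' channel; `adjusted = tx - variability`, significant when positive.
#'
#' @param pop,reference matrices (population and unlabeled events).
#' @param variability named per-channel variability (see
#'   [control_variability()]).
#' @param B_requested requested bins.
#' @return data frame with `channel`, `tx`, `control`, `adjusted`,
#'   `significant`.
#' @export
adjusted_tx_table <- function(pop, reference, variability, B_requested = 100) {
  pop <- event_values(pop); reference <- event_values(reference)
  ch <- colnames(reference)
  rows <- lapply(ch, function(c_) {
    tx <- tx_compare(reference[, c_], pop[, c_], B_requested)$tx
    v <- if (c_ %in% names(variability)) variability[[c_]] else 0
    data.frame(channel = c_, tx = tx, control = v, adjusted = tx - v,
               significant = tx - v > 0)
  })
  do.call(rbind, rows)
}

#' Marker positivity and phenotype call for a population
#'
#' A channel is called positive when its control-adjusted T(x) against the
#' unlabeled reference is significant AND the population median exceeds
#' the reference's 99th percentile (the statistical difference must point
#' upward, not merely reflect spread). The positivity pattern maps to a
#' named phenotype; channels absent from the panel count as negative.
#'
#' @param pop population event matrix.
#' @param reference unlabeled-cell event matrix.
#' @param variability named per-channel control variability.
#' @param B_requested requested bins.
#' @param q reference quantile a positive median must clear.
#' @return list with `positive` (named logical), `phenotype`, `table`.
#' @export
marker_positivity <- function(pop, reference, variability = NULL,
                              B_requested = 100, q = 0.99) {
  pop <- event_values(pop); reference <- event_values(reference)
  ch <- colnames(reference)
  if (is.null(variability)) variability <- stats::setNames(rep(0, length(ch)), ch)
  tab <- adjusted_tx_table(pop, reference, variability, B_requested)
  above <- vapply(ch, function(c_)
    stats::median(pop[, c_]) > stats::quantile(reference[, c_], q), logical(1))
  positive <- stats::setNames(tab$significant & above, ch)
  tab$positive <- unname(positive)
  is_pos <- function(c_) c_ %in% names(positive) && positive[[c_]]
  cd45 <- is_pos("CD45"); cd31 <- is_pos("CD31"); pdpn <- is_pos("PDPN")
  icam <- is_pos("ICAM1"); vcam <- is_pos("VCAM1")
  phenotype <-
    if (cd45 && cd31 && pdpn && icam && vcam) "hematopoietic"
    else if (!cd45 && cd31 && pdpn && icam && vcam) "LEC"
    else if (!cd45 && !cd31 && !pdpn && !icam && vcam) "PvC"
    else if (!cd45 && !cd31 && pdpn && !icam && vcam) "FRC"
    else if (!cd45 && !cd31 && pdpn && icam && vcam) "MRC-like"
    else "unassigned"
  list(positive = positive, phenotype = phenotype, table = tab)
}

#' Passage-resolved population table
#'
#' @param counts integer matrix: populations (rows) by passages (columns);
#'   column names are passage numbers.
#' @return data frame with overall and per-passage counts and percentages
#'   (of total labeled cells and of each passage's cells, rounded half-up
#'   to 2 decimals) plus a totals row.
#' @export
passage_table <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  pas_tot <- colSums(counts)
  out <- data.frame(population = rownames(counts),
                    n_total = rowSums(counts),
                    pct_total = round_half_up(100 * rowSums(counts) / total, 2))
  for (p in colnames(counts)) {
    out[[paste0("n_P", p)]] <- counts[, p]
    out[[paste0("pct_P", p)]] <- round_half_up(100 * counts[, p] / pas_tot[p], 2)
  }
  tot_row <- data.frame(population = "Total labeled cells", n_total = total,
                        pct_total = NA_real_)
  for (p in colnames(counts)) {
    tot_row[[paste0("n_P", p)]] <- pas_tot[p]
    tot_row[[paste0("pct_P", p)]] <- NA_real_
  }
  structure(rbind(out, tot_row), class = c("population_table", "data.frame"))
}

#' Population/passage table of a consensus result
#'
#' Counts labeled-cell populations by passage (controls are excluded, as in
#' a labeled-cells-only breakdown).
#'
#' @param p a `consensus_populations` object.
#' @return a [passage_table()].
#' @export
population_table <- function(p) {
  lab <- p$meta$sample_type == "labeled_cells" & grepl("^pop_", p$labels)
  if (!any(lab))
    cc_stop("no labeled-cell populations to tabulate", "cc_parameter_error")
  tb <- table(p$labels[lab], p$meta$passage[lab])
  m <- matrix(as.integer(tb), nrow(tb), ncol(tb), dimnames = dimnames(tb))
  passage_table(m)
}

#' Render a population table as aligned text
#' @param tbl a [passage_table()].
#' @return character vector of lines.
#' @export
format_population_table <- function(tbl) {
  cols <- names(tbl)
  w <- vapply(cols, function(c_) max(nchar(c_), nchar(format(tbl[[c_]]))), integer(1))
  fmt_row <- function(vals) paste(mapply(function(v, wi) formatC(v, width = wi),
                                         vals, w), collapse = "  ")
  c(fmt_row(cols),
    vapply(seq_len(nrow(tbl)), function(i)
      fmt_row(vapply(cols, function(c_) {
        v <- tbl[[c_]][i]
        if (is.numeric(v) && !is.na(v) && grepl("^pct", c_)) sprintf("%.2f", v)
        else if (is.na(v)) "" else as.character(v)
      }, character(1))), character(1)))
}
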