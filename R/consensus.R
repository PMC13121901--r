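## Consensus population identification. The manual procedure -- eyeballing
## agreement among clustering algorithms across embeddings, anchoring on
## bead controls, then merging clusters that differ by no more than control
## variability -- is formalized as: (1) a co-association matrix over the
## clusterings, cut by average linkage; (2) control anchoring by sample
## composition; (3) a pairwise merge loop gated on the control-adjusted
## probability-binning T(x) and a robust effect-size guard; (4) a
## cross-embedding island-consistency diagnostic.

#' Co-association matrix over several clusterings
#'
#' @param clusterings list of at least two `clustering_result`s over the
#'   same events.
#' @param subsample cap on the number of events entering the matrix
#'   (uniform, seeded).
#' @param seed integer seed.
#' @return a `coassociation` object: `idx` (subsampled event indices) and
#'   symmetric matrix `M` of pairwise same-cluster fractions.
#' @export
build_coassociation <- function(clusterings, subsample = 5000, seed = 1) {
  if (length(clusterings) < 2)
    cc_stop("co-association requires at least two clusterings", "cc_parameter_error")
  ns <- vapply(clusterings, function(cl) length(cl$labels), integer(1))
  if (length(unique(ns)) != 1)
    cc_stop("clusterings cover different event sets", "cc_parameter_error")
  n <- ns[1]
  idx <- if (n > subsample) with_seed(seed, sort(sample.int(n, subsample))) else seq_len(n)
  M <- matrix(0, length(idx), length(idx))
  for (cl in clusterings) {
    L <- cl$labels[idx]
    M <- M + outer(L, L, "==")
  }
  M <- M / length(clusterings)
  structure(list(idx = idx, M = M, n_clusterings = length(clusterings), n_events = n),
            class = "coassociation")
}

#' Consensus partition from a co-association matrix
#'
#' Average-linkage hierarchical grouping on `1 - coassociation`, cut at
#' height `1 - cut`; groups smaller than `min_size` subsampled events are
#' dissolved into the nearest surviving group's centroid. When the marker
#' matrix `m` is supplied, events outside the subsample are assigned to the
#' nearest group centroid in marker space.
#'
#' @param coassoc a [build_coassociation()] result.
#' @param m optional [event_matrix()] (transformed scale) over all events,
#'   used for centroid extension.
#' @param cut co-association fraction at which groups separate; events
#'   co-clustered by at least this fraction of algorithms stay together.
#' @param min_size minimum subsampled events per group.
#' @return list with `labels` (all events, when `m` given; otherwise the
#'   subsample), `subsample_labels`, `idx` and `cut`.
#' @export
consensus_partition <- function(coassoc, m = NULL, cut = 0.5, min_size = 5) {
  hc <- stats::hclust(stats::as.dist(1 - coassoc$M), method = "average")
  ## average linkage is monotone; clamp floating-point height inversions
  hc$height <- cummax(hc$height)
  g <- stats::cutree(hc, h = 1 - cut)
  X <- if (!is.null(m)) event_values(m) else NULL
  sizes <- table(g)
  small <- as.integer(names(sizes)[sizes < min_size])
  if (length(small) > 0 && length(small) < length(sizes) && !is.null(X)) {
    Xs <- X[coassoc$idx, , drop = FALSE]
    keepg <- setdiff(as.integer(names(sizes)), small)
    cent <- rowsum(Xs[g %in% keepg, , drop = FALSE], g[g %in% keepg]) /
      as.vector(table(g[g %in% keepg]))
    bad <- g %in% small
    g[bad] <- keepg[best_matching_unit(Xs[bad, , drop = FALSE], cent)]
  }
  g <- match(g, sort(unique(g)))
  labels <- NULL
  if (!is.null(X)) {
    cent <- rowsum(X[coassoc$idx, , drop = FALSE], g) / as.vector(table(g))
    labels <- best_matching_unit(X, cent)
    labels[coassoc$idx] <- g
  }
  list(labels = labels %||% g, subsample_labels = g, idx = coassoc$idx, cut = cut)
}

#' Robust standardized separation between two clusters
#'
#' Per channel, the absolute median difference divided by the pooled scaled
#' median absolute deviation; the aggregate is the maximum over channels.
#' Channels whose pooled MAD collapses are floored at `mad_floor_frac`
#' times the channel's overall MAD.
#'
#' @param m an [event_matrix()] or matrix.
#' @param labels per-event cluster labels.
#' @param a,b cluster ids to compare.
#' @param mad_floor_frac floor fraction for degenerate spreads.
#' @return list with `per_channel` distances and `aggregate`.
#' @export
cluster_similarity <- function(m, labels, a, b, mad_floor_frac = 0.05) {
  X <- event_values(m)
  ia <- labels == a; ib <- labels == b
  if (!any(ia) || !any(ib))
    cc_stop("both clusters must be non-empty", "cc_parameter_error")
  per <- vapply(seq_len(ncol(X)), function(j) {
    xa <- X[ia, j]; xb <- X[ib, j]
    pooled <- sqrt((stats::mad(xa)^2 + stats::mad(xb)^2) / 2)
    floor_j <- max(mad_floor_frac * stats::mad(X[, j]), 1e-8)
    abs(stats::median(xa) - stats::median(xb)) / max(pooled, floor_j)
  }, numeric(1))
  names(per) <- colnames(X)
  list(per_channel = per, aggregate = max(per))
}

## per-event metadata data.frame from an assembled_dataset
assembled_meta <- function(ad) {
  data.frame(sample_id = ad$sample_id, sample_type = ad$sample_type,
              stain_channel = ad$stain_channel, day = ad$day,
              passage = ad$passage, stringsAsFactors = FALSE)
}

#' Anchor clusters on controls and merge indistinct populations
#'
#' Stage 1 (anchoring): a cluster with at least `anchor_fraction` of its
#' events from bead samples is a bead cluster; it becomes
#' `bead_control(<channel>)` when one single-stain sample dominates it and
#' its signal on that channel is high, otherwise `negative_beads`.
#' Clusters dominated by unlabeled-cell events are `unlabeled_cells`.
#' Clusters of the same control role merge. Stage 2 (labeled merge): the
#' remaining labeled-cell clusters are tested pairwise, smallest id pair
#' first; a pair merges when its control-adjusted T(x) is at most 0 on
#' every channel AND the robust separation aggregate is below
#' `similarity_threshold`, repeating to a fixed point. Pairs that pass the
#' T(x) rule but fail the separation guard are flagged `borderline` in the
#' audit log. Every decision is recorded.
#'
#' @param m an [event_matrix()] over all events.
#' @param labels per-event consensus cluster labels.
#' @param meta per-event metadata data frame (columns `sample_id`,
#'   `sample_type`, `stain_channel`, `day`, `passage`), e.g. from an
#'   assembled dataset.
#' @param control_variability named per-channel T(x) variability levels (see
#'   [control_variability()]); zero for every channel when `NULL`.
#' @param anchor_fraction control-composition fraction that anchors a
#'   cluster.
#' @param similarity_threshold robust-separation merge guard (units of
#'   pooled scaled MAD).
#' @param b_request requested probability bins for the pairwise T(x).
#' @param min_merge_n below this pair size the T(x) is untestable (bin rule)
#'   and the pair is judged on separation alone.
#' @return a `consensus_populations` object: per-event `labels` (population
#'   names), `roles` table, `audit` log, `control_variability`.
#' @export
anchor_and_merge <- function(m, labels, meta, control_variability = NULL,
                             anchor_fraction = 0.9, similarity_threshold = 2,
                             b_request = 100, min_merge_n = 20) {
  X <- event_values(m)
  ch <- colnames(X)
  if (is.null(control_variability))
    control_variability <- stats::setNames(rep(0, length(ch)), ch)
  audit <- list()
  note <- function(stage, action, a, b = NA, detail = "") {
    audit[[length(audit) + 1]] <<- data.frame(
      stage = stage, action = action, cluster_a = as.character(a),
      cluster_b = as.character(b), detail = detail)
  }
  has_controls <- any(meta$sample_type != "labeled_cells")
  if (!has_controls) warning("no control samples present; anchoring skipped")

  ids <- sort(unique(labels))
  role <- stats::setNames(rep("labeled_population", length(ids)), ids)
  role_channel <- stats::setNames(rep(NA_character_, length(ids)), ids)
  bead_all <- meta$sample_type == "bead_single_stain"
  for (id in ids) {
    in_c <- labels == id
    f_bead <- mean(bead_all[in_c])
    f_unl <- mean(meta$sample_type[in_c] == "unlabeled_cells")
    if (f_unl >= anchor_fraction) {
      role[as.character(id)] <- "unlabeled_cells"
      note("anchor", "role_unlabeled", id)
    } else if (f_bead >= anchor_fraction) {
      tab <- sort(table(meta$stain_channel[in_c & bead_all]), decreasing = TRUE)
      dom <- names(tab)[1]
      dom_frac <- tab[1] / sum(in_c)
      high_signal <- dom %in% ch &&
        stats::median(X[in_c, dom]) > stats::median(X[bead_all, dom])
      if (dom_frac >= anchor_fraction && high_signal) {
        role[as.character(id)] <- "bead_control"
        role_channel[as.character(id)] <- dom
        note("anchor", "role_bead_control", id, detail = dom)
      } else {
        role[as.character(id)] <- "negative_beads"
        note("anchor", "role_negative_beads", id)
      }
    } else if (max(f_bead, f_unl, mean(meta$sample_type[in_c] == "labeled_cells")) <
               anchor_fraction) {
      note("anchor", "mixed_composition", id,
           detail = sprintf("bead %.2f unlabeled %.2f", f_bead, f_unl))
    }
  }
  ## merge clusters sharing a control role
  merged <- labels
  role_key <- ifelse(role == "bead_control", paste0("bead_control:", role_channel), role)
  for (key in unique(role_key[role_key != "labeled_population"])) {
    members <- as.integer(names(role_key)[role_key == key])
    if (length(members) > 1) {
      for (b in members[-1]) {
        merged[merged == b] <- members[1]
        note("anchor", "merge_same_role", members[1], b, key)
      }
    }
  }

  ## stage 2: pairwise labeled merge to a fixed point
  repeat {
    lids <- sort(unique(merged[role[as.character(merged)] == "labeled_population"]))
    did_merge <- FALSE
    if (length(lids) >= 2) {
      pairs <- utils::combn(lids, 2)
      for (pi_ in seq_len(ncol(pairs))) {
        a <- pairs[1, pi_]; b <- pairs[2, pi_]
        ia <- merged == a; ib <- merged == b
        na <- sum(ia); nb <- sum(ib)
        sim <- cluster_similarity(X, merged, a, b)
        if (min(na, nb) >= min_merge_n) {
          adj <- vapply(ch, function(c_) {
            tx_compare(X[ia, c_], X[ib, c_], b_request)$tx - control_variability[[c_]]
          }, numeric(1))
          tx_ok <- all(adj <= 0)
          tx_note <- sprintf("max adjusted tx %.2f", max(adj))
        } else {
          tx_ok <- TRUE
          tx_note <- "pair too small for binning; separation rule only"
        }
        if (tx_ok && sim$aggregate < similarity_threshold) {
          merged[ib] <- a
          note("merge", "merge", a, b,
               sprintf("%s; separation %.2f", tx_note, sim$aggregate))
          did_merge <- TRUE
          break
        } else if (tx_ok && sim$aggregate >= similarity_threshold) {
          note("merge", "borderline", a, b,
               sprintf("%s but separation %.2f >= %.2f", tx_note,
                       sim$aggregate, similarity_threshold))
        }
      }
    }
    if (!did_merge) break
  }

  ## final naming: controls first, labeled populations by decreasing size
  final_ids <- sort(unique(merged))
  final_role <- role[as.character(final_ids)]
  final_chan <- role_channel[as.character(final_ids)]
  name <- character(length(final_ids))
  name[final_role == "bead_control"] <- paste0("bead_", final_chan[final_role == "bead_control"])
  name[final_role == "negative_beads"] <- "negative_beads"
  name[final_role == "unlabeled_cells"] <- "unlabeled_cells"
  lab_ids <- final_ids[final_role == "labeled_population"]
  lab_sizes <- vapply(lab_ids, function(id) sum(merged == id), integer(1))
  name[match(lab_ids[order(-lab_sizes)], final_ids)] <-
    paste0("pop_", seq_along(lab_ids))
  pop_labels <- name[match(merged, final_ids)]
  roles <- data.frame(population = name, role = unname(final_role),
                      channel = unname(final_chan),
                      n_events = vapply(final_ids, function(id) sum(merged == id),
                                        integer(1)))
  roles <- roles[order(roles$role != "bead_control", roles$population), ]
  rownames(roles) <- NULL
  structure(list(labels = pop_labels, roles = roles,
                 audit = do.call(rbind, audit),
                 control_variability = control_variability,
                 meta = meta),
            class = "consensus_populations")
}

#' @export
print.consensus_populations <- function(x, ...) {
  cat(sprintf("<consensus_populations> %d events, %d populations\n",
              length(x$labels), nrow(x$roles)))
  print(x$roles)
  invisible(x)
}

#' Number of consensus populations
#' @param p a `consensus_populations` object.
#' @return integer count of distinct populations (control roles plus
#'   labeled-cell populations).
#' @export
n_populations <- function(p) nrow(p$roles)

#' Cross-embedding island consistency of consensus populations
#'
#' For every population and embedding, the best Jaccard overlap between the
#' population and any density island of the layout; the score is the
#' fraction of embeddings where that overlap reaches `jaccard_min`.
#'
#' @param p a `consensus_populations` object.
#' @param e an `embedding_set` over the same events.
#' @param bandwidth,density_quantile island-detection parameters (see
#'   [detect_islands()]).
#' @param jaccard_min overlap counted as "the population is its own
#'   island".
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
cross_embedding_consistency <- function(p, e, bandwidth = NULL,
                                        density_quantile = 0.25,
                                        jaccard_min = 0.5) {
  n <- length(p$labels)
  if (any(vapply(e$layouts, nrow, integer(1)) != n))
    cc_stop("embeddings must cover the same events as the populations",
            "cc_parameter_error")
  pops <- unique(p$labels)
  hits <- matrix(0, length(pops), length(e$layouts),
                 dimnames = list(pops, names(e$layouts)))
  for (li in seq_along(e$layouts)) {
    isl <- detect_islands(e$layouts[[li]], bandwidth, density_quantile)
    for (pi_ in seq_along(pops)) {
      A <- p$labels == pops[pi_]
      best <- 0
      for (id in setdiff(unique(isl), 0L)) {
        B <- isl == id
        j <- sum(A & B) / sum(A | B)
        if (j > best) best <- j
      }
      hits[pi_, li] <- best >= jaccard_min
    }
  }
  rowMeans(hits)
}
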