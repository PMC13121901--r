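## Configuration-driven pipeline: simulate/load -> bead normalization ->
## gating variation baseline -> pooled dataset -> three clusterings ->
## co-association consensus -> control anchoring and T(x)-gated merging ->
## phenotypes and the passage-resolved population table, with an optional
## embedding consistency diagnostic and a CSV/report output bundle.

#' Parameter presets for the clustering/embedding stage
#'
#' `"low"`, `"default"` and `"high"` presets varying the SOM grid and
#' metacluster count and the neighbourhood sizes, used by the robustness
#' sweep to emulate users picking different algorithm parameters.
#'
#' @param level `"low"`, `"default"` or `"high"`.
#' @return named list of parameters.
#' @export
highdim_params <- function(level = c("default", "low", "high")) {
  level <- match.arg(level)
  switch(level,
    low = list(grid = c(6, 6), k_meta = 5, k_neighbors = 15),
    default = list(grid = c(10, 10), k_meta = 7, k_neighbors = 30),
    high = list(grid = c(14, 14), k_meta = 10, k_neighbors = 50))
}

#' Pipeline configuration
#'
#' Validated up front: a directory-mode configuration whose directory does
#' not exist fails here, before any computation.
#'
#' @param mode `"synthetic"` (simulate from `design`) or `"directory"`
#'   (read a study written by [write_study()]).
#' @param design a [study_design()] (synthetic mode).
#' @param dir study directory (directory mode).
#' @param out_dir output directory for the report bundle; `NULL` writes
#'   nothing.
#' @param seed master seed; every stage's seed derives from it.
#' @param normalize run bead-anchored normalization.
#' @param gating_variants list of [gating_criteria()] for the traditional
#'   gating baseline (fewer than two skips the variation study).
#' @param variant [dataset_variant()] assembled for the high-dimensional
#'   stage.
#' @param transform [transform_spec()].
#' @param level highdim parameter preset used when `ensemble = FALSE`.
#' @param ensemble feed the consensus all nine clusterings (three
#'   algorithms at the low/default/high presets), mirroring the practice of
#'   comparing arrays of runs across parameter choices; `FALSE` uses the
#'   three clusterings of `level` only.
#' @param cut co-association cut.
#' @param anchor_fraction,similarity_threshold,b_request consensus / T(x)
#'   parameters.
#' @param cluster_subsample events clustered directly; the consensus
#'   partition is extended to the rest by nearest centroid.
#' @param embeddings compute the embedding suite and island consistency.
#' @param embed_n events embedded (subset of the clustering subsample).
#' @param config_file path of the source config file, for provenance.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(mode = c("synthetic", "directory"), design = NULL,
                            dir = NULL, out_dir = NULL, seed = 1,
                            normalize = TRUE,
                            gating_variants = list(
                              gating_criteria(0.995), gating_criteria(0.999),
                              gating_criteria(1.0)),
                            variant = dataset_variant("all", "all"),
                            transform = transform_spec(),
                            level = "default", ensemble = TRUE, cut = 0.5,
                            anchor_fraction = 0.9, similarity_threshold = 2,
                            b_request = 100, cluster_subsample = 4000,
                            embeddings = FALSE, embed_n = 2000,
                            config_file = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && !inherits(design, "study_design"))
    cc_stop("synthetic mode requires a study_design", "cc_parameter_error")
  if (mode == "directory") {
    if (is.null(dir) || !dir.exists(dir))
      cc_stop(paste0("study directory does not exist: ", dir %||% "<missing>"),
              "cc_parameter_error")
  }
  structure(list(mode = mode, design = design, dir = dir, out_dir = out_dir,
                 seed = as.integer(seed), normalize = normalize,
                 gating_variants = gating_variants, variant = variant,
                 transform = transform, level = level, ensemble = ensemble,
                 cut = cut,
                 anchor_fraction = anchor_fraction,
                 similarity_threshold = similarity_threshold,
                 b_request = b_request, cluster_subsample = cluster_subsample,
                 embeddings = embeddings, embed_n = embed_n,
                 config_file = config_file),
            class = "pipeline_config")
}

#' Read a flat key = value pipeline configuration file
#'
#' Recognized keys: `mode`, `dir`, `out_dir`, `seed`, `n_cells`, `n_beads`,
#' `separation`, `mrc_fraction`, `batch_gain`, `batch_offset`,
#' `batch_channel`, `normalize`, `retention` (comma-separated), `level`,
#' `cut`, `cluster_subsample`, `embeddings`. Lines starting with `#` are
#' comments.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) cc_stop(paste0("no such config: ", path), "cc_parameter_error")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(m) != 3) cc_stop(paste0("unparseable config line: ", l), "cc_parameter_error")
    kv[[m[2]]] <- trimws(m[3])
  }
  num <- function(k, d) if (is.null(kv[[k]])) d else as.numeric(kv[[k]])
  chr <- function(k, d) if (is.null(kv[[k]])) d else kv[[k]]
  lgl <- function(k, d) if (is.null(kv[[k]])) d else tolower(kv[[k]]) %in% c("true", "1", "yes")
  mode <- chr("mode", "synthetic")
  design <- NULL
  if (mode == "synthetic") {
    design <- reference_design(
      n_cells = num("n_cells", 20000), n_beads = num("n_beads", 5000),
      separation = chr("separation", "well_separated"),
      mrc_fraction = num("mrc_fraction", 0),
      batch_gain = num("batch_gain", 0.4), batch_offset = num("batch_offset", 15),
      batch_channel = chr("batch_channel", "ICAM1"))
  }
  ret <- as.numeric(strsplit(chr("retention", "0.995,0.999,1.0"), ",")[[1]])
  pipeline_config(
    mode = mode, design = design, dir = chr("dir", NULL),
    out_dir = chr("out_dir", NULL), seed = num("seed", 1),
    normalize = lgl("normalize", TRUE),
    gating_variants = lapply(ret, gating_criteria),
    level = chr("level", "default"), cut = num("cut", 0.5),
    cluster_subsample = num("cluster_subsample", 4000),
    embeddings = lgl("embeddings", FALSE),
    config_file = path)
}

#' Density-balanced event subsample
#'
#' Samples events with probability inversely proportional to their local
#' density (inverse mean distance to the k nearest neighbours), so rare,
#' tight populations keep representation that a uniform draw would starve
#' them of -- the reason the pooled datasets use all events rather than
#' equal-size caps.
#'
#' @param X numeric matrix of event vectors.
#' @param n_out target subsample size.
#' @param k density neighbourhood.
#' @param seed integer seed.
#' @return sorted integer row indices.
#' @export
balanced_subsample <- function(X, n_out, k = 15, seed = 1) {
  n <- nrow(X)
  if (n <= n_out) return(seq_len(n))
  d <- RANN::nn2(X, k = min(k, n - 1) + 1)$nn.dists[, -1, drop = FALSE]
  w <- pmax(rowMeans(d), .Machine$double.eps)  # inverse density
  w <- pmin(w, stats::quantile(w, 0.99))       # cap outlier weights
  seeds <- derive_seeds(seed, 2)
  ## half uniform (dense groups keep representation), half density-weighted
  ## (rare tight populations are not starved)
  n_unif <- floor(n_out / 2)
  take <- with_seed(seeds[1], sample.int(n, n_unif))
  rest <- setdiff(seq_len(n), take)
  take2 <- with_seed(seeds[2], rest[sample.int(length(rest), n_out - n_unif,
                                               prob = w[rest])])
  sort(c(take, take2))
}

## three clusterings at a parameter preset, over a (sub)matrix
run_clusterings <- function(tm_sub, pars, seeds) {
  list(
    som = som_cluster(tm_sub, grid = pars$grid, k_meta = pars$k_meta, seed = seeds[1]),
    graph = graph_community_cluster(tm_sub, k_neighbors = pars$k_neighbors,
                                    seed = seeds[2]),
    density = density_peak_cluster(tm_sub, k_neighbors = pars$k_neighbors))
}

#' Run the full consensus pipeline
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a `pipeline_result` with every stage's output:
#'   `study` (normalized), `normalization`, `gating`, `assembled`,
#'   `clusterings`, `populations` (a `consensus_populations`),
#'   `phenotypes`, `table`, `consistency` and `paths` of written files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) cc_stop("not a pipeline_config",
                                                    "cc_parameter_error")
  seeds <- derive_seeds(config$seed, 8)
  study <- if (config$mode == "synthetic")
    generate_study(config$design, seeds[1]) else read_study(config$dir)

  norm <- NULL
  if (config$normalize) {
    norm <- normalize_study(study)
    study <- norm$study
  }

  gating <- NULL
  if (length(config$gating_variants) >= 2)
    gating <- gating_variation_study(study, config$gating_variants)

  ad <- assemble_dataset(study, config$variant, seed = seeds[2])
  tm <- apply_transform(ad$events, config$transform)

  sub_idx <- balanced_subsample(tm$values, config$cluster_subsample, seed = seeds[3])
  tm_sub <- event_matrix(tm$values[sub_idx, , drop = FALSE], tm$panel, "transformed")

  cls <- if (isTRUE(config$ensemble)) {
    lv <- c("low", "default", "high")
    s4 <- derive_seeds(seeds[4], 2 * length(lv))
    out <- list()
    for (i in seq_along(lv)) {
      one <- run_clusterings(tm_sub, highdim_params(lv[i]),
                             s4[c(2 * i - 1, 2 * i)])
      names(one) <- paste0(names(one), "_", lv[i])
      out <- c(out, one)
    }
    out
  } else {
    run_clusterings(tm_sub, highdim_params(config$level), derive_seeds(seeds[4], 2))
  }
  coassoc <- build_coassociation(cls, subsample = length(sub_idx), seed = seeds[5])
  part <- consensus_partition(coassoc, m = tm_sub, cut = config$cut)

  ## extend the subsample partition to every event by nearest centroid
  g <- part$labels
  cent <- rowsum(tm_sub$values, g) / as.vector(table(g))
  full_labels <- best_matching_unit(tm$values, cent)
  full_labels[sub_idx] <- g

  cv <- control_variability(study, config$b_request)
  pops <- anchor_and_merge(tm, full_labels, assembled_meta(ad),
                           control_variability = cv$variability,
                           anchor_fraction = config$anchor_fraction,
                           similarity_threshold = config$similarity_threshold,
                           b_request = config$b_request)

  ## phenotypes and passage table for the labeled populations
  unl_ref <- tm$values[ad$sample_type == "unlabeled_cells", , drop = FALSE]
  phen <- list()
  for (p in unique(pops$labels[grepl("^pop_", pops$labels)])) {
    phen[[p]] <- marker_positivity(tm$values[pops$labels == p, , drop = FALSE],
                                   unl_ref, cv$variability, config$b_request)
  }
  phenotypes <- vapply(phen, function(x) x$phenotype, character(1))
  tbl <- population_table(pops)

  consistency <- NULL; embeds <- NULL
  if (config$embeddings) {
    emb_local <- if (length(sub_idx) > config$embed_n)
      with_seed(seeds[6], sort(sample.int(length(sub_idx), config$embed_n)))
      else seq_along(sub_idx)
    emb_idx <- sub_idx[emb_local]
    emb_m <- event_matrix(tm$values[emb_idx, , drop = FALSE], tm$panel, "transformed")
    embeds <- embed_suite(emb_m, seed = seeds[7])
    p_sub <- structure(list(labels = pops$labels[emb_idx]),
                       class = "consensus_populations")
    consistency <- cross_embedding_consistency(p_sub, embeds)
  }

  res <- structure(list(
    study = study, normalization = norm, gating = gating, assembled = ad,
    clusterings = cls, coassociation = coassoc, partition = part,
    control_variability = cv, populations = pops, phenotype_detail = phen,
    phenotypes = phenotypes, table = tbl, embeddings = embeds,
    consistency = consistency, config = config, paths = NULL
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) res$paths <- write_bundle(res, config$out_dir)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d populations identified\n", n_populations(x$populations)))
  if (!is.null(x$gating))
    cat(sprintf("  traditional gating mean CV: %.1f%%\n", x$gating$mean_cv))
  invisible(x)
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  cfg <- res$config
  if (!is.null(res$normalization)) put(res$normalization$report, "normalization_report.csv")
  if (!is.null(res$gating)) {
    put(data.frame(population = rownames(res$gating$counts), res$gating$counts,
                   cv_pct = res$gating$cv), "gating_cv.csv")
  }
  put(data.frame(event = seq_along(res$populations$labels),
                 sample_id = res$assembled$sample_id,
                 population = res$populations$labels), "consensus_labels.csv")
  put(res$populations$roles, "population_roles.csv")
  if (!is.null(res$populations$audit)) put(res$populations$audit, "merge_audit.csv")
  put(data.frame(control = rownames(res$control_variability$table),
                 res$control_variability$table, check.names = FALSE),
      "control_tx_table.csv")
  put(res$table, "population_table.csv")
  txt <- file.path(out_dir, "population_table.txt")
  writeLines(format_population_table(res$table), txt)
  paths <- c(paths, txt)
  if (!is.null(res$consistency))
    put(data.frame(population = names(res$consistency), score = res$consistency),
        "embedding_consistency.csv")
  hash <- if (!is.null(cfg$config_file)) unname(tools::md5sum(cfg$config_file)) else NA
  log <- c(sprintf("seed = %d", cfg$seed),
           sprintf("level = %s", cfg$level),
           sprintf("cut = %.3f", cfg$cut),
           sprintf("config_md5 = %s", hash),
           sprintf("populations = %d", n_populations(res$populations)),
           sprintf("phenotypes: %s",
                   paste(names(res$phenotypes), res$phenotypes, sep = "=",
                         collapse = ", ")))
  logp <- file.path(out_dir, "run_log.txt")
  writeLines(log, logp)
  c(paths, logp)
}

#' Consensus robustness sweep
#'
#' Emulates users re-running the high-dimensional analysis with different
#' algorithm parameters (presets) and different consensus cuts (the analog
#' of dragging a gate). Labeled populations of every run are matched to the
#' reference run (default preset, middle cut) by nearest centroid in
#' transformed marker space; per preset, the CV of each matched
#' population's count across cuts is computed, and the preset's mean CV is
#' reported along with the sweep-wide mean.
#'
#' @param study a (normalized) [study_set()].
#' @param levels parameter presets to sweep.
#' @param cuts consensus cuts to sweep.
#' @param seed master seed.
#' @param variant,transform,cluster_subsample,anchor_fraction,similarity_threshold,b_request
#'   as in [pipeline_config()].
#' @return list with `per_level` mean CVs, `overall_mean_cv`, and the raw
#'   `counts` array (population x cut x level).
#' @export
consensus_variation_study <- function(study, levels = c("low", "default", "high"),
                                      cuts = c(0.4, 0.5, 0.6), seed = 1,
                                      variant = dataset_variant("all", "all"),
                                      transform = transform_spec(),
                                      cluster_subsample = 4000,
                                      anchor_fraction = 0.9,
                                      similarity_threshold = 2, b_request = 100) {
  seeds <- derive_seeds(seed, 4 + length(levels))
  ad <- assemble_dataset(study, variant, seed = seeds[1])
  tm <- apply_transform(ad$events, transform)
  sub_idx <- balanced_subsample(tm$values, cluster_subsample, seed = seeds[2])
  tm_sub <- event_matrix(tm$values[sub_idx, , drop = FALSE], tm$panel, "transformed")
  cvar <- control_variability(study, b_request)
  meta <- assembled_meta(ad)

  one_run <- function(cls, cut) {
    coassoc <- build_coassociation(cls, subsample = length(sub_idx), seed = seeds[3])
    part <- consensus_partition(coassoc, m = tm_sub, cut = cut)
    g <- part$labels
    cent <- rowsum(tm_sub$values, g) / as.vector(table(g))
    full <- best_matching_unit(tm$values, cent)
    full[sub_idx] <- g
    pops <- anchor_and_merge(tm, full, meta, control_variability = cvar$variability,
                             anchor_fraction = anchor_fraction,
                             similarity_threshold = similarity_threshold,
                             b_request = b_request)
    lab <- grepl("^pop_", pops$labels)
    ids <- unique(pops$labels[lab])
    cents <- t(vapply(ids, function(id)
      matrixStats::colMedians(tm$values[pops$labels == id, , drop = FALSE]),
      numeric(ncol(tm$values))))
    counts <- vapply(ids, function(id) sum(pops$labels == id), integer(1))
    list(ids = ids, centroids = cents, counts = counts)
  }

  ref_cls <- run_clusterings(tm_sub, highdim_params("default"),
                             derive_seeds(seeds[4], 2))
  ref <- one_run(ref_cls, cuts[ceiling(length(cuts) / 2)])

  match_counts <- function(run) {
    out <- stats::setNames(numeric(length(ref$ids)), ref$ids)
    if (length(run$ids) == 0) return(out)
    nearest <- best_matching_unit(run$centroids, ref$centroids)
    for (k in seq_along(run$ids))
      out[nearest[k]] <- out[nearest[k]] + run$counts[k]
    out
  }

  per_level <- stats::setNames(numeric(length(levels)), levels)
  counts_arr <- array(NA_real_, c(length(ref$ids), length(cuts), length(levels)),
                      dimnames = list(ref$ids, as.character(cuts), levels))
  for (li in seq_along(levels)) {
    cls <- if (levels[li] == "default") ref_cls else
      run_clusterings(tm_sub, highdim_params(levels[li]),
                      derive_seeds(seeds[4 + li], 2))
    for (ci in seq_along(cuts))
      counts_arr[, ci, li] <- match_counts(one_run(cls, cuts[ci]))
    per_level[li] <- mean(apply(counts_arr[, , li, drop = FALSE], 1, count_cv),
                          na.rm = TRUE)
  }
  list(per_level = per_level, overall_mean_cv = mean(per_level, na.rm = TRUE),
       counts = counts_arr)
}
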