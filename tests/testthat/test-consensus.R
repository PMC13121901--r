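fake_cl <- function(labels) {
  structure(list(method = "fake", labels = as.integer(labels),
                 n_clusters = length(unique(labels)), params = list(),
                 seed = NA_integer_), class = "clustering_result")
}

test_that("co-association reproduces the hand-enumerated example", {
  # events A B C D; partitions {AB|CD}, {AB|CD}, {AC|BD}
  cls <- list(fake_cl(c(1, 1, 2, 2)), fake_cl(c(1, 1, 2, 2)),
              fake_cl(c(1, 2, 1, 2)))
  co <- build_coassociation(cls, subsample = 10, seed = 1)
  expect_equal(co$M[1, 2], 2 / 3)
  expect_equal(co$M[1, 3], 1 / 3)
  expect_true(isSymmetric(co$M))
  expect_true(all(diag(co$M) == 1))
  expect_true(all(co$M >= 0 & co$M <= 1))
  expect_error(build_coassociation(cls[1]), class = "cc_parameter_error")
  expect_error(build_coassociation(list(fake_cl(1:3), fake_cl(1:4))),
               class = "cc_parameter_error")
})

test_that("consensus partition recovers agreement and honors the cut", {
  cls <- list(fake_cl(rep(1:3, each = 20)), fake_cl(rep(1:3, each = 20)))
  co <- build_coassociation(cls)
  for (cut in c(0.25, 0.5, 0.75)) {
    p <- consensus_partition(co, cut = cut, min_size = 1)
    expect_equal(ari(p$labels, rep(1:3, each = 20)), 1.0)
  }
  # cut 0 merges everything
  p0 <- consensus_partition(co, cut = 0, min_size = 1)
  expect_identical(length(unique(p0$labels)), 1L)
  # the 4-event example at cut 0.5 groups {A,B} and {C,D}
  cls4 <- list(fake_cl(c(1, 1, 2, 2)), fake_cl(c(1, 1, 2, 2)),
               fake_cl(c(1, 2, 1, 2)))
  p4 <- consensus_partition(build_coassociation(cls4), cut = 0.5, min_size = 1)
  expect_identical(p4$labels[1], p4$labels[2])
  expect_identical(p4$labels[3], p4$labels[4])
  expect_false(p4$labels[1] == p4$labels[3])
})

test_that("nearest-centroid extension covers events outside the subsample", {
  b <- blob_matrix(n_per = 400, centers = 2, seed = 23)
  cl <- list(density_peak_cluster(b$m, 20), som_cluster(b$m, k_meta = 2, seed = 1))
  co <- build_coassociation(cl, subsample = 200, seed = 5)
  p <- consensus_partition(co, m = b$m, cut = 0.5)
  expect_length(p$labels, 800L)
  expect_equal(ari(p$labels, b$truth), 1.0)
})

test_that("robust separation behaves like a standardized distance", {
  x <- withr::with_seed(31, matrix(stats::rnorm(4000), 2000, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  labels <- rep(1:2, each = 1000)
  s_same <- cluster_similarity(x, labels, 1, 2)
  expect_lt(s_same$aggregate, 0.5)
  x2 <- x
  x2[labels == 2, 1] <- x2[labels == 2, 1] + 10  # 10 robust-SD offset
  s_off <- cluster_similarity(x2, labels, 1, 2)
  expect_lt(abs(s_off$aggregate - 10) / 10, 0.15)
  s_ba <- cluster_similarity(x2, labels, 2, 1)
  expect_equal(s_off$aggregate, s_ba$aggregate)
  expect_error(cluster_similarity(x, labels, 1, 3), class = "cc_parameter_error")
})

test_that("anchoring assigns control roles and merges same-distribution splits", {
  st <- generate_study(small_design(n_cells = 2000, n_beads = 600), seed = 41)
  st <- normalize_study(st)$study
  ad <- assemble_dataset(st, dataset_variant("all", "all"), seed = 1)
  tm <- apply_transform(ad$events)
  truth <- unlist(lapply(st$samples, function(s) s$truth))
  stain <- rep(vapply(st$samples, function(s) s$meta$stain_channel, character(1)),
               vapply(st$samples, function(s) n_events(s$events), integer(1)))
  # build labels from generator truth, with the FRC population randomly
  # split in two: the split must merge, the rest must anchor
  key <- ifelse(truth %in% c("pos_bead", "neg_bead"), paste0(truth, "_", stain), truth)
  labels <- as.integer(factor(key))
  frc <- which(truth == "FRC")
  split <- withr::with_seed(42, sample(frc, length(frc) / 2))
  labels[split] <- max(labels) + 1L
  cvar <- control_variability(st)
  pops <- anchor_and_merge(tm, labels, cytoconsensus:::assembled_meta(ad),
                           control_variability = cvar$variability)
  roles <- pops$roles
  expect_identical(sum(roles$role == "bead_control"), 5L)
  expect_setequal(roles$channel[roles$role == "bead_control"], channels(tm))
  expect_identical(sum(roles$role == "negative_beads"), 1L)
  expect_identical(sum(roles$role == "unlabeled_cells"), 1L)
  # the random FRC split was merged back: 4 labeled populations remain
  expect_identical(sum(roles$role == "labeled_population"), 4L)
  expect_true(any(pops$audit$action == "merge"))
  # no merge across generator truth boundaries
  tab <- table(truth[ad$sample_type == "labeled_cells"],
               pops$labels[ad$sample_type == "labeled_cells"])
  purity <- apply(tab, 2, function(col) max(col) / sum(col))
  expect_true(all(purity > 0.95))
})

test_that("separated populations never merge across truth boundaries", {
  for (sd in 1:10) {
    b <- blob_matrix(n_per = 300, centers = 3, seed = 600 + sd)
    meta <- data.frame(sample_id = "s", sample_type = "labeled_cells",
                       stain_channel = NA, day = 1, passage = 5)[rep(1, 900), ]
    pops <- suppressWarnings(anchor_and_merge(b$m, b$truth, meta))
    expect_identical(sum(pops$roles$role == "labeled_population"), 3L)
  }
})

test_that("merging is insensitive to cluster id permutation", {
  b <- blob_matrix(n_per = 200, centers = 3, seed = 71)
  labels <- b$truth
  extra <- withr::with_seed(72, sample(which(labels == 1), 100))
  labels[extra] <- 4L
  meta <- data.frame(sample_id = "s", sample_type = "labeled_cells",
                     stain_channel = NA, day = 1, passage = 5)[rep(1, 600), ]
  p1 <- suppressWarnings(anchor_and_merge(b$m, labels, meta))
  relab <- c(3L, 1L, 4L, 2L)[labels]
  p2 <- suppressWarnings(anchor_and_merge(b$m, relab, meta))
  expect_equal(ari(p1$labels, p2$labels), 1.0)
  expect_identical(nrow(p1$roles), nrow(p2$roles))
})

test_that("cross-embedding consistency scores are sane", {
  b <- blob_matrix(n_per = 300, centers = 2, d = 4, seed = 81)
  es <- embed_suite(b$m, algorithms = c("trimap", "pacmap"), seed = 2)
  pops <- structure(list(labels = as.character(b$truth)),
                    class = "consensus_populations")
  sc <- cross_embedding_consistency(pops, es, density_quantile = 0.1)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(sc == 1))
  # a population scattered uniformly across the layout scores ~0
  scat <- as.character(b$truth)
  idx <- withr::with_seed(83, sample(600, 60))
  scat[idx] <- "scattered"
  sc2 <- cross_embedding_consistency(
    structure(list(labels = scat), class = "consensus_populations"), es,
    density_quantile = 0.1)
  expect_equal(unname(sc2["scattered"]), 0)
})
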