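test_that("embedding suite is shaped, deterministic and separates blobs", {
  b <- blob_matrix(n_per = 150, centers = 2, d = 5, seed = 5)
  es <- embed_suite(b$m, seed = 3)
  expect_setequal(names(es$layouts), c("tsne", "umap", "trimap", "pacmap"))
  for (nm in names(es$layouts)) {
    expect_equal(dim(es$layouts[[nm]]), c(300L, 2L))
    expect_true(all(is.finite(es$layouts[[nm]])))
    sil <- cluster::silhouette(b$truth, stats::dist(es$layouts[[nm]]))
    expect_gt(mean(sil[, "sil_width"]), 0.5)
  }
  es2 <- embed_suite(b$m, seed = 3)
  for (nm in names(es$layouts))
    expect_identical(es$layouts[[nm]], es2$layouts[[nm]])
  expect_error(embed_suite(b$m, algorithms = "isomap"), class = "cc_parameter_error")
  lin <- event_matrix(b$m$values, b$m$panel, "linear")
  expect_error(embed_suite(lin), class = "cc_parameter_error")
})

test_that("SOM metaclustering caps clusters and recovers separated blobs", {
  b <- blob_matrix(n_per = 250, centers = 2, seed = 7)
  cl <- som_cluster(b$m, grid = c(6, 6), k_meta = 2, seed = 2)
  expect_lte(cl$n_clusters, 2L)
  expect_equal(ari(cl$labels, b$truth), 1.0)
  cl2 <- som_cluster(b$m, grid = c(6, 6), k_meta = 2, seed = 2)
  expect_identical(cl$labels, cl2$labels)
  cl7 <- som_cluster(b$m, k_meta = 7, seed = 1)
  expect_lte(cl7$n_clusters, 7L)
  expect_error(som_cluster(b$m, k_meta = 0), class = "cc_parameter_error")
  expect_error(som_cluster(b$m, grid = c(2, 2), k_meta = 5), class = "cc_parameter_error")
})

test_that("graph communities recover separated blobs exactly", {
  b <- blob_matrix(n_per = 200, centers = 3, seed = 9)
  cl <- graph_community_cluster(b$m, k_neighbors = 30, seed = 4)
  expect_identical(cl$n_clusters, 3L)
  expect_equal(ari(cl$labels, b$truth), 1.0)
  expect_identical(sort(unique(cl$labels)), 1:3)
  # complete-graph limit on one tight blob collapses to one community
  one <- blob_matrix(n_per = 60, centers = 1, sd = 0.1, seed = 2)
  cl1 <- graph_community_cluster(one$m, k_neighbors = 59, seed = 1)
  expect_identical(cl1$n_clusters, 1L)
  expect_error(graph_community_cluster(one$m, k_neighbors = 60),
               class = "cc_parameter_error")
})

test_that("density-peak clustering follows the density gradient", {
  b <- blob_matrix(n_per = 250, centers = 2, seed = 11)
  cl <- density_peak_cluster(b$m, k_neighbors = 100)
  expect_identical(cl$n_clusters, 2L)
  expect_equal(ari(cl$labels, b$truth), 1.0)

  # strictly monotone 1-D density chain with k = 1 collapses to one cluster
  gaps <- 1 / (1:40)
  x <- cbind(c(0, cumsum(gaps)))
  cl1 <- density_peak_cluster(x, k_neighbors = 1)
  expect_identical(cl1$n_clusters, 1L)
  # brute-force density oracle: nearest-gap density rises along the chain
  nnd <- sapply(seq_len(nrow(x)), function(i) min(abs(x[-i, 1] - x[i, 1])))
  dens <- 1 / nnd
  expect_true(all(diff(dens[1:40]) > 0))

  # invariance to event order up to label renaming
  perm <- withr::with_seed(8, sample.int(nrow(b$m$values)))
  clp <- density_peak_cluster(b$m$values[perm, ], k_neighbors = 100)
  expect_equal(ari(clp$labels, cl$labels[perm]), 1.0)
})

test_that("cluster roots are local density maxima among their neighbours", {
  b <- blob_matrix(n_per = 150, centers = 2, seed = 13)
  X <- b$m$values
  k <- 20
  nn <- RANN::nn2(X, k = k + 1)
  dens <- 1 / rowMeans(nn$nn.dists[, -1])
  cl <- density_peak_cluster(X, k_neighbors = k)
  for (g in unique(cl$labels)) {
    members <- which(cl$labels == g)
    root <- members[which.max(dens[members])]
    nb <- nn$nn.idx[root, -1]
    expect_true(all(dens[nb] < dens[root] |
                    (dens[nb] == dens[root] & nb > root)))
  }
})

test_that("the three clusterers agree on a well-separated mixture", {
  b <- blob_matrix(n_per = 150, centers = 4, seed = 17)
  cls <- list(som_cluster(b$m, k_meta = 4, seed = 1),
              graph_community_cluster(b$m, seed = 1),
              density_peak_cluster(b$m))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(ari(cls[[i]]$labels, cls[[j]]$labels), 0.95)
})

test_that("island detection separates and covers a layout", {
  pts <- withr::with_seed(19, rbind(matrix(stats::rnorm(800), 400, 2),
                                    matrix(stats::rnorm(800) + 20, 400, 2)))
  isl <- detect_islands(pts, bandwidth = 1, density_quantile = 0.2)
  fg <- isl[isl > 0]
  expect_identical(length(unique(fg)), 2L)
  expect_identical(length(isl), 800L)
  # quantile 0 on a single connected cloud keeps everything in one island
  one <- withr::with_seed(20, matrix(stats::rnorm(1000), 500, 2))
  isl0 <- detect_islands(one, bandwidth = 1, density_quantile = 0)
  expect_identical(unique(isl0), 1L)
})
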