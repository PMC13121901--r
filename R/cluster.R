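## Three clusterers with deliberately different inductive biases, run on the
## full-dimensional transformed event vectors:
##   * som_cluster       -- batch self-organizing map + hierarchical
##                          metaclustering of the codebook (conservative;
##                          the cluster count is user-capped)
##   * graph_community_cluster -- shared-nearest-neighbour graph + Louvain
##                          modularity communities (density-area seeking)
##   * density_peak_cluster -- ascend to the nearest denser neighbour
##                          (rare-population sensitive, deterministic)
## Their disagreement is a signal the consensus stage exploits.

new_clustering_result <- function(method, labels, params, seed = NA_integer_) {
  labels <- as.integer(labels)
  ## contiguous ids 1..K preserving order of first appearance magnitude
  u <- sort(unique(labels))
  labels <- match(labels, u)
  structure(list(method = method, labels = labels, n_clusters = length(u),
                 params = params, seed = seed), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s: %d events in %d clusters\n",
              x$method, length(x$labels), x$n_clusters))
  invisible(x)
}

event_values <- function(m) {
  if (inherits(m, "event_matrix")) m$values else as.matrix(m)
}

#' Self-organizing-map metaclustering
#'
#' Trains a batch SOM on the event vectors (Gaussian neighbourhood with a
#' shrinking radius), agglomerates the node codebook by average-linkage
#' hierarchical clustering into `k_meta` metaclusters, and assigns each
#' event its best-matching node's metacluster.
#'
#' @param m an [event_matrix()] or numeric matrix.
#' @param grid `c(rows, cols)` of the map.
#' @param k_meta number of metaclusters (at most `prod(grid)`).
#' @param seed integer seed (codebook initialization).
#' @param rlen training epochs.
#' @return a `clustering_result`.
#' @export
som_cluster <- function(m, grid = c(10, 10), k_meta = 7, seed = 1, rlen = 10) {
  X <- event_values(m)
  n <- nrow(X)
  ncodes <- prod(grid)
  if (k_meta < 1) cc_stop("k_meta must be at least 1", "cc_parameter_error")
  if (k_meta > ncodes) cc_stop("k_meta exceeds the number of SOM nodes", "cc_parameter_error")
  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  gdist2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  codes <- with_seed(seed, X[sample.int(n, ncodes, replace = n < ncodes), , drop = FALSE])
  codes <- codes + with_seed(seed + 1L, matrix(stats::rnorm(length(codes), 0, 1e-6),
                                               nrow(codes)))
  radii <- seq(max(grid) / 2, 0.5, length.out = rlen)
  bmu <- integer(n)
  for (ep in seq_len(rlen)) {
    bmu <- best_matching_unit(X, codes)
    cnt <- tabulate(bmu, ncodes)
    sums <- rowsum(X, bmu)
    S <- matrix(0, ncodes, ncol(X))
    S[as.integer(rownames(sums)), ] <- sums
    H <- exp(-gdist2 / (2 * radii[ep]^2))
    denom <- as.vector(H %*% cnt)
    newcodes <- (H %*% S) / denom
    keep <- denom <= 1e-12
    if (any(keep)) newcodes[keep, ] <- codes[keep, ]
    codes <- newcodes
  }
  bmu <- best_matching_unit(X, codes)
  meta <- stats::cutree(stats::hclust(stats::dist(codes), method = "average"), k = k_meta)
  new_clustering_result("som_meta", meta[bmu],
                        list(grid = grid, k_meta = k_meta, rlen = rlen), seed)
}

## chunked nearest-codebook assignment
best_matching_unit <- function(X, codes, chunk = 20000L) {
  n <- nrow(X)
  cn2 <- rowSums(codes^2)
  out <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    G <- X[s:e, , drop = FALSE] %*% t(codes)
    D <- sweep(-2 * G, 2, cn2, "+")
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' Shared-nearest-neighbour community clustering
#'
#' Builds a k-nearest-neighbour graph (Euclidean), weights each edge by the
#' Jaccard overlap of the endpoints' neighbour lists, and partitions it
#' with Louvain modularity maximization.
#'
#' @param m an [event_matrix()] or numeric matrix.
#' @param k_neighbors neighbourhood size (must be below the event count).
#' @param seed integer seed for the community detection.
#' @return a `clustering_result`.
#' @export
graph_community_cluster <- function(m, k_neighbors = 30, seed = 1) {
  X <- event_values(m)
  n <- nrow(X)
  if (n < 5) cc_stop("too few events for graph clustering", "cc_parameter_error")
  k <- min(k_neighbors, n - 1)
  if (k_neighbors >= n)
    cc_stop("k_neighbors must be below the number of events", "cc_parameter_error")
  nn <- RANN::nn2(X, k = k + 1)$nn.idx
  ## neighbour sets include self (column 1)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  edges_i <- rep(seq_len(n), k)
  edges_j <- as.vector(nn[, -1])
  shared <- as.vector(Matrix::rowSums(A[edges_i, ] * A[edges_j, ]))
  jacc <- shared / (2 * (k + 1) - shared)
  und <- edges_i < edges_j
  el <- cbind(ifelse(und, edges_i, edges_j), ifelse(und, edges_j, edges_i))
  dup <- duplicated(el)
  g <- igraph::graph_from_edgelist(el[!dup, , drop = FALSE], directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = jacc[!dup])
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  new_clustering_result("graph_community", memb, list(k_neighbors = k_neighbors), seed)
}

#' Density-peak clustering
#'
#' Per-event density is the inverse mean distance to its k nearest
#' neighbours; each event links to its nearest higher-density neighbour
#' within its neighbour list; events with none are density peaks and the
#' trees rooted at peaks are the clusters. Fully deterministic; density
#' ties are broken by event index (lower index counts as denser).
#'
#' @param m an [event_matrix()] or numeric matrix.
#' @param k_neighbors neighbourhood size (below the event count).
#' @return a `clustering_result`.
#' @export
density_peak_cluster <- function(m, k_neighbors = 30) {
  X <- event_values(m)
  n <- nrow(X)
  if (k_neighbors >= n)
    cc_stop("k_neighbors must be below the number of events", "cc_parameter_error")
  k <- k_neighbors
  nn <- RANN::nn2(X, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  d <- nn$nn.dists[, -1, drop = FALSE]
  dens <- 1 / pmax(rowMeans(d), .Machine$double.eps)
  self <- seq_len(n)
  denser <- matrix(dens[idx], n, k) > dens[self] |
    (matrix(dens[idx], n, k) == dens[self] & idx < self)
  ## nearest (columns are distance-ordered) denser neighbour; 0 = peak
  has <- rowSums(denser) > 0
  first <- max.col(denser, ties.method = "first")
  parent <- self
  parent[has] <- idx[cbind(self[has], first[has])]
  ## resolve to roots
  while (TRUE) {
    gp <- parent[parent]
    if (identical(gp, parent)) break
    parent <- gp
  }
  new_clustering_result("density_peak", match(parent, sort(unique(parent))),
                        list(k_neighbors = k_neighbors))
}
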