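## 2-D embeddings with four different local/global-structure trade-offs.
## tSNE and UMAP wrap Rtsne and uwot; the triplet and pair embedders are
## compact implementations of the published TriMap and PaCMAP procedures
## (nearest-neighbour triplets / three pair classes with phase-scheduled
## weights), sufficient for the role embeddings play here: visualization
## and the island-consistency diagnostic, never the population labels.

embedding_algorithms <- c("tsne", "umap", "trimap", "pacmap")

#' Compute a suite of 2-D embeddings
#'
#' @param m an [event_matrix()] on the transformed scale (at least 50
#'   events).
#' @param algorithms subset of `"tsne"`, `"umap"`, `"trimap"`, `"pacmap"`.
#' @param seed integer seed; layouts are deterministic given it.
#' @param params optional named list of per-algorithm parameter overrides.
#' @return an `embedding_set`: named list of `n x 2` layouts plus the seed
#'   and parameter record.
#' @export
embed_suite <- function(m, algorithms = embedding_algorithms, seed = 1,
                        params = list()) {
  if (inherits(m, "event_matrix") && m$scale != "transformed")
    cc_stop("embeddings expect transformed-scale data", "cc_parameter_error")
  X <- event_values(m)
  n <- nrow(X)
  if (n < 50) cc_stop("embedding requires at least 50 events", "cc_parameter_error")
  bad <- setdiff(algorithms, embedding_algorithms)
  if (length(bad))
    cc_stop(paste0("unknown embedding algorithm: ", paste(bad, collapse = ", ")),
            "cc_parameter_error")
  layouts <- list()
  used <- list()
  for (alg in algorithms) {
    p <- params[[alg]]
    if (alg == "tsne") {
      perplexity <- p$perplexity %||% min(30, floor((n - 1) / 3))
      fit <- with_seed(seed, Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                                          check_duplicates = FALSE, pca = TRUE,
                                          max_iter = p$max_iter %||% 500,
                                          num_threads = 1))
      layouts[[alg]] <- fit$Y
      used[[alg]] <- list(perplexity = perplexity)
    } else if (alg == "umap") {
      nnb <- p$n_neighbors %||% min(15, n - 1)
      layouts[[alg]] <- with_seed(seed, uwot::umap(
        X, n_neighbors = nnb, min_dist = p$min_dist %||% 0.1,
        n_threads = 1, n_sgd_threads = 1, verbose = FALSE))
      used[[alg]] <- list(n_neighbors = nnb)
    } else if (alg == "trimap") {
      layouts[[alg]] <- trimap_embed(X, seed = seed,
                                     n_inliers = p$n_inliers %||% 10,
                                     n_outliers = p$n_outliers %||% 5,
                                     n_iters = p$n_iters %||% 250)
      used[[alg]] <- list(n_inliers = p$n_inliers %||% 10)
    } else {
      layouts[[alg]] <- pacmap_embed(X, seed = seed,
                                     n_neighbors = p$n_neighbors %||% 10,
                                     n_iters = p$n_iters %||% 300)
      used[[alg]] <- list(n_neighbors = p$n_neighbors %||% 10)
    }
    dimnames(layouts[[alg]]) <- NULL
  }
  structure(list(layouts = layouts, seed = seed, params = used),
            class = "embedding_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pca2 <- function(X) {
  Y <- stats::prcomp(X, rank. = 2)$x
  if (ncol(Y) < 2) Y <- cbind(Y, 0)
  Y
}

## accumulate per-pair 2-D gradient contributions onto points
acc_grad <- function(G, idx, contrib, n) {
  s <- rowsum(contrib, idx)
  G[as.integer(rownames(s)), ] <- G[as.integer(rownames(s)), ] + s
  G
}

#' Triplet embedding (TriMap-style)
#'
#' For each point, triplets (i, j, k) pair a near neighbour j with sampled
#' far points k; the layout minimizes `s_ik / (s_ij + s_ik)` with
#' `s = 1 / (1 + d^2)`, by full-batch gradient descent with momentum from a
#' PCA initialization. Unit triplet weights (a simplification of the
#' published weighting).
#'
#' @param X numeric matrix.
#' @param n_inliers neighbours per point.
#' @param n_outliers sampled far points per neighbour pair.
#' @param n_iters gradient iterations.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return `n x 2` layout.
#' @export
trimap_embed <- function(X, n_inliers = 10, n_outliers = 5, n_iters = 250,
                         lr = 0.4, seed = 1) {
  n <- nrow(X)
  n_inliers <- min(n_inliers, n - 2)
  nn <- RANN::nn2(X, k = n_inliers + 1)$nn.idx[, -1, drop = FALSE]
  ti <- rep(seq_len(n), each = n_inliers * n_outliers)
  tj <- rep(as.vector(t(nn)), each = n_outliers)
  tk <- with_seed(seed, sample.int(n, length(ti), replace = TRUE))
  fix <- tk == ti | tk == tj
  tk[fix] <- (tk[fix] %% n) + 1L
  Y <- pca2(X)
  Y <- Y / stats::sd(Y[, 1])
  V <- matrix(0, n, 2)
  for (it in seq_len(n_iters)) {
    u <- Y[ti, ] - Y[tj, ]
    v <- Y[ti, ] - Y[tk, ]
    sij <- 1 / (1 + rowSums(u^2))
    sik <- 1 / (1 + rowSums(v^2))
    S2 <- (sij + sik)^2
    cu <- 2 * sij^2 * sik / S2
    cv <- -2 * sij * sik^2 / S2
    gu <- u * cu
    gv <- v * cv
    G <- matrix(0, n, 2)
    G <- acc_grad(G, ti, gu + gv, n)
    G <- acc_grad(G, tj, -gu, n)
    G <- acc_grad(G, tk, -gv, n)
    V <- 0.8 * V - lr * G
    Y <- Y + V
  }
  Y
}

#' Pairwise embedding (PaCMAP-style)
#'
#' Optimizes attraction on nearest-neighbour pairs, mid-near pairs (second
#' closest of a small random draw) and repulsion on random further pairs,
#' with the published three-phase weight schedule, via Adam from a scaled
#' PCA initialization.
#'
#' @param X numeric matrix.
#' @param n_neighbors near-pair count per point.
#' @param mn_ratio,fp_ratio mid-near and further-pair counts as ratios of
#'   `n_neighbors`.
#' @param n_iters gradient iterations.
#' @param seed integer seed.
#' @return `n x 2` layout.
#' @export
pacmap_embed <- function(X, n_neighbors = 10, mn_ratio = 0.5, fp_ratio = 2,
                         n_iters = 300, seed = 1) {
  n <- nrow(X)
  k <- min(n_neighbors, n - 2)
  nn <- RANN::nn2(X, k = k + 1)$nn.idx[, -1, drop = FALSE]
  nb_i <- rep(seq_len(n), k); nb_j <- as.vector(nn)
  n_mn <- max(1L, round(k * mn_ratio))
  n_fp <- max(1L, round(k * fp_ratio))
  seeds <- derive_seeds(seed, 2)
  mn <- with_seed(seeds[1], {
    cand <- matrix(sample.int(n, n * n_mn * 6, replace = TRUE), ncol = 6)
    ci <- rep(seq_len(n), each = n_mn)
    d2 <- sapply(1:6, function(c_) rowSums((X[ci, , drop = FALSE] -
                                            X[cand[, c_], , drop = FALSE])^2))
    ord <- apply(d2, 1, function(r) order(r)[2])
    cand[cbind(seq_len(nrow(cand)), ord)]
  })
  mn_i <- rep(seq_len(n), each = n_mn); mn_j <- mn
  fp_j <- with_seed(seeds[2], sample.int(n, n * n_fp, replace = TRUE))
  fp_i <- rep(seq_len(n), n_fp)
  ok <- fp_j != fp_i
  fp_i <- fp_i[ok]; fp_j <- fp_j[ok]

  Y <- pca2(X) * 0.01
  mo <- matrix(0, n, 2); ve <- matrix(0, n, 2)
  b1 <- 0.9; b2 <- 0.999; lr <- 1
  p1 <- round(n_iters * 0.22); p2 <- round(n_iters * 0.45)
  for (it in seq_len(n_iters)) {
    if (it <= p1) {
      w_nb <- 2; w_mn <- 1000 * (1 - it / p1) + 3 * it / p1; w_fp <- 1
    } else if (it <= p2) {
      w_nb <- 3; w_mn <- 3; w_fp <- 1
    } else {
      w_nb <- 1; w_mn <- 0; w_fp <- 1
    }
    G <- matrix(0, n, 2)
    u <- Y[nb_i, ] - Y[nb_j, ]
    co <- w_nb * 20 / (10 + rowSums(u^2))^2
    G <- acc_grad(G, nb_i, u * co, n); G <- acc_grad(G, nb_j, -u * co, n)
    if (w_mn > 0) {
      u <- Y[mn_i, ] - Y[mn_j, ]
      co <- w_mn * 20000 / (10000 + rowSums(u^2))^2
      G <- acc_grad(G, mn_i, u * co, n); G <- acc_grad(G, mn_j, -u * co, n)
    }
    u <- Y[fp_i, ] - Y[fp_j, ]
    co <- -w_fp * 2 / (1 + rowSums(u^2))^2
    G <- acc_grad(G, fp_i, u * co, n); G <- acc_grad(G, fp_j, -u * co, n)
    mo <- b1 * mo + (1 - b1) * G
    ve <- b2 * ve + (1 - b2) * G^2
    Y <- Y - lr * (mo / (1 - b1^it)) / (sqrt(ve / (1 - b2^it)) + 1e-7)
  }
  Y
}

#' Detect density islands in a 2-D layout
#'
#' Gaussian kernel density at each point (against a capped reference
#' subset); points at or above the `density_quantile` of those densities
#' are foreground, and islands are the connected components of the
#' foreground under a fixed-radius neighbour graph.
#'
#' @param layout `n x 2` coordinates.
#' @param bandwidth kernel bandwidth; default is the normal-reference rule
#'   averaged over the two axes.
#' @param density_quantile foreground quantile in `[0, 1)`; 0 keeps every
#'   point.
#' @param link_radius component-linking radius; default `2 * bandwidth`.
#' @return integer vector: island id per event, 0 for background.
#' @export
detect_islands <- function(layout, bandwidth = NULL, density_quantile = 0.25,
                           link_radius = NULL) {
  layout <- as.matrix(layout)
  n <- nrow(layout)
  if (is.null(bandwidth))
    bandwidth <- mean(apply(layout, 2, stats::bw.nrd))
  if (is.null(link_radius)) link_radius <- 2 * bandwidth
  ref_idx <- unique(round(seq(1, n, length.out = min(n, 2000))))
  ref <- layout[ref_idx, , drop = FALSE]
  dens <- numeric(n)
  chunk <- 20000L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(rowSums(layout[s:e, , drop = FALSE]^2), rowSums(ref^2), "+") -
      2 * layout[s:e, , drop = FALSE] %*% t(ref)
    dens[s:e] <- rowMeans(exp(-pmax(d2, 0) / (2 * bandwidth^2)))
  }
  fg <- dens >= stats::quantile(dens, density_quantile)
  labels <- integer(n)
  pts <- layout[fg, , drop = FALSE]
  if (nrow(pts) == 0) return(labels)
  nnr <- RANN::nn2(pts, k = min(30L, nrow(pts)), searchtype = "radius",
                   radius = link_radius)$nn.idx
  src <- rep(seq_len(nrow(pts)), ncol(nnr))
  dst <- as.vector(nnr)
  keep <- dst > 0
  g <- igraph::graph_from_edgelist(cbind(src[keep], dst[keep]), directed = FALSE)
  if (igraph::vcount(g) < nrow(pts))
    g <- igraph::add_vertices(g, nrow(pts) - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}
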