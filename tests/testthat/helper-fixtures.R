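# Shared fixtures: small study designs and simple generated matrices.

small_design <- function(n_cells = 2000, n_beads = 600, ...) {
  reference_design(n_cells = n_cells, n_beads = n_beads, ...)
}

# well-separated Gaussian blobs in d dimensions, `sep` SDs apart along the
# first axis chain
make_blobs <- function(n_per, centers, d = 5, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(centers), function(k) {
      mu <- c(rep(0, d))
      mu[1] <- (k - 1) * 10 * sd
      mu[min(k, d)] <- mu[min(k, d)] + (k - 1) * 5 * sd
      matrix(stats::rnorm(n_per * d, mean = rep(mu, each = n_per), sd = sd), n_per, d)
    }))
    list(X = X, truth = rep(seq_len(centers), each = n_per))
  })
}

blob_matrix <- function(n_per, centers, d = 5, sd = 1, seed = 1) {
  b <- make_blobs(n_per, centers, d, sd, seed)
  m <- event_matrix(b$X, channel_panel(paste0("ch", seq_len(d))), "linear")
  m$scale <- "transformed"
  list(m = m, truth = b$truth)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
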