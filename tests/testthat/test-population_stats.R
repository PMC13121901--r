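test_that("probability bins honor the 10% cap and equal occupancy", {
  x <- withr::with_seed(1, stats::rlnorm(2453, 5, 1))
  b <- probability_bins(x, 1000)
  expect_identical(b$B, 245L)
  b4 <- probability_bins(as.numeric(1:100), 4)
  counts <- tabulate(bin_assign(b4, as.numeric(1:100)), 4)
  expect_identical(counts, rep(25L, 4))
  # equal occupancy up to integer rounding on continuous data
  y <- withr::with_seed(2, stats::rnorm(5000))
  b50 <- probability_bins(y, 50)
  cts <- tabulate(bin_assign(b50, y), 50)
  expect_lte(max(cts) - min(cts), 1L)
  expect_error(probability_bins(stats::rnorm(15), 4), class = "cc_parameter_error")
})

test_that("multivariate median-split bins partition the space", {
  X <- withr::with_seed(3, matrix(stats::rnorm(3000), 1000, 3))
  b <- probability_bins(X, 32)
  expect_identical(b$B, 32L)
  test_pts <- withr::with_seed(4, matrix(stats::rnorm(1500, sd = 3), 500, 3))
  ids <- bin_assign(b, test_pts)
  expect_true(all(ids >= 1 & ids <= 32))
  expect_length(ids, 500L)
  # exhaustive point-in-leaf check: descending the tree by hand gives the
  # same leaf for every point
  descend <- function(p) {
    node <- 1L
    while (!b$tree[[node]]$leaf) {
      nd <- b$tree[[node]]
      node <- if (p[nd$channel] <= nd$cutoff) nd$left else nd$right
    }
    b$leaf_no[node]
  }
  manual <- apply(test_pts, 1, descend)
  expect_identical(ids, manual)
  ctrl_counts <- tabulate(bin_assign(b, X), 32)
  expect_true(all(ctrl_counts > 0))
})

test_that("T(x) is zero on self-comparison and large on a unit shift", {
  x <- withr::with_seed(5, stats::rnorm(10000))
  expect_equal(tx_compare(x, x, 100)$tx, 0)
  y <- withr::with_seed(6, stats::rnorm(10000) + 1)
  r <- tx_compare(x, y, 100)
  expect_gt(r$tx, 10)
  expect_identical(r$B, 100L)
  # brute-force chi-squared oracle on the same quantile bins
  edges <- stats::quantile(x, seq_len(99) / 100)
  cb <- tabulate(findInterval(x, edges) + 1L, 100)
  tb <- tabulate(findInterval(y, edges) + 1L, 100)
  p <- (cb + tb) / 20000
  chi2 <- sum((cb - 10000 * p)^2 / (10000 * p) + (tb - 10000 * p)^2 / (10000 * p))
  expect_equal(r$chi2, chi2, tolerance = 0.05)
  expect_error(tx_score(probability_bins(x, 100), x, numeric(0)),
               class = "cc_parameter_error")
})

test_that("null calibration: same-distribution T(x) stays near zero", {
  txs <- withr::with_seed(7, vapply(1:200, function(i) {
    a <- stats::rlnorm(10000, 4, 1); b <- stats::rlnorm(10000, 4, 1)
    tx_compare(a, b, 100)$tx
  }, numeric(1)))
  expect_lt(abs(mean(txs)), 0.3)
  expect_lt(mean(txs > 3), 0.05)
})

test_that("Monte-Carlo null moments agree with the analytic reference", {
  x <- withr::with_seed(8, stats::rnorm(2000))
  y <- withr::with_seed(9, stats::rnorm(2000))
  bins <- probability_bins(x, 50)
  mc <- tx_score(bins, x, y, null = "montecarlo", mc_reps = 400, seed = 2)
  expect_lt(abs(mc$null_mean - 49) / 49, 0.1)
  expect_lt(abs(mc$null_sd - sqrt(98)) / sqrt(98), 0.25)
})

test_that("T(x) is invariant under monotone transforms of both samples", {
  x <- withr::with_seed(10, stats::rlnorm(4000, 4, 1))
  y <- withr::with_seed(11, stats::rlnorm(6000, 4.2, 1.1))
  r1 <- tx_compare(x, y, 80)
  r2 <- tx_compare(asinh(x / 150), asinh(y / 150), 80)
  expect_equal(r1$chi2, r2$chi2)
  expect_equal(r1$tx, r2$tx)
  # bin cap honored in every emitted result
  expect_lte(r1$B, floor(min(length(x), length(y)) / 10))
})

test_that("control variability applies the exclusion rule", {
  st <- generate_study(small_design(n_cells = 2000, n_beads = 800), seed = 51)
  st <- normalize_study(st)$study
  cv <- control_variability(st)
  expect_setequal(names(cv$variability), channels(st))
  expect_true(all(cv$variability >= 0))
  # any control excluded on a channel must exceed the unlabeled T(x) there
  for (ch in channels(st)) {
    exc <- cv$excluded[, ch]
    if (any(exc))
      expect_true(all(cv$table[exc, ch] > cv$table["unlabeled_cells", ch]))
    expect_lte(cv$variability[[ch]], cv$table["unlabeled_cells", ch])
  }
  # unlabeled cells are never excluded from their own reference
  expect_true(all(!cv$excluded["unlabeled_cells", ]))
})

test_that("a shifted population is significant only on the shifted channel", {
  ref <- withr::with_seed(12, matrix(stats::rlnorm(30000, 4, 0.5), 10000, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  pop <- withr::with_seed(13, matrix(stats::rlnorm(6000, 4, 0.5), 2000, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  pop[, "b"] <- pop[, "b"] * 12  # >5 robust-SD shift on the asinh scale
  vars <- c(a = 2, b = 2, c = 2)
  tab <- adjusted_tx_table(asinh(pop / 150), asinh(ref / 150), vars)
  expect_true(tab$significant[tab$channel == "b"])
  expect_false(any(tab$significant[tab$channel != "b"]))
})

test_that("marker positivity maps patterns to phenotypes", {
  n <- 4000
  base <- function(seed) withr::with_seed(seed, stats::rlnorm(n, log(100), 0.5))
  hi <- function(seed) withr::with_seed(seed, stats::rlnorm(n, log(5000), 0.4))
  ref <- cbind(CD45 = base(1), CD31 = base(2), PDPN = base(3),
               ICAM1 = base(4), VCAM1 = base(5))
  tr <- function(m) asinh(m / 150)
  # drawn from the reference distribution: unassigned, all negative
  popref <- cbind(CD45 = base(6), CD31 = base(7), PDPN = base(8),
                  ICAM1 = base(9), VCAM1 = base(10))
  mp0 <- marker_positivity(tr(popref), tr(ref))
  expect_false(any(mp0$positive))
  expect_identical(mp0$phenotype, "unassigned")
  # VCAM1-only positive: perivascular
  pvc <- popref; pvc[, "VCAM1"] <- hi(11)
  expect_identical(marker_positivity(tr(pvc), tr(ref))$phenotype, "PvC")
  # CD31+ PDPN+ ICAM1+ VCAM1+ (CD45-): lymphatic endothelial
  lec <- popref
  for (ch in c("CD31", "PDPN", "ICAM1", "VCAM1")) lec[, ch] <- hi(match(ch, colnames(lec)) + 20)
  expect_identical(marker_positivity(tr(lec), tr(ref))$phenotype, "LEC")
  # all five: hematopoietic
  hem <- lec; hem[, "CD45"] <- hi(30)
  expect_identical(marker_positivity(tr(hem), tr(ref))$phenotype, "hematopoietic")
})

test_that("passage table reproduces printed-count arithmetic exactly", {
  counts <- matrix(c(7052, 4910, 366, 77922,
                     8, 252, 5388, 86660), ncol = 2,
                   dimnames = list(paste0("Population ", 1:4), c("5", "12")))
  tbl <- passage_table(counts)
  expect_equal(tbl$n_total[1:4], c(7060, 5162, 5754, 164582))
  expect_equal(tbl$pct_total[1:4], c(3.87, 2.83, 3.15, 90.15))
  expect_equal(tbl$pct_P5[1:4], c(7.81, 5.44, 0.41, 86.34))
  expect_equal(tbl$pct_P12[1:4], c(0.01, 0.27, 5.84, 93.88))
  expect_equal(tbl$n_total[5], 182558)
  expect_equal(tbl$n_P5[5], 90250)
  expect_equal(tbl$n_P12[5], 92308)
  # percentages re-derive exactly from the table's own counts
  expect_equal(tbl$pct_total[1:4],
               round_half_up(100 * tbl$n_total[1:4] / tbl$n_total[5], 2))
  # single population: 100.00 of total
  one <- passage_table(matrix(c(10, 20), 1, 2, dimnames = list("p", c("5", "12"))))
  expect_equal(one$pct_total[1], 100)
  txt <- format_population_table(tbl)
  expect_length(txt, 6L)
})
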