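test_that("peak detection splits degenerate and lognormal mixtures", {
  v <- c(rep(100, 300), rep(10000, 300))
  pp <- detect_control_peaks(v)
  expect_equal(pp$low, 100)
  expect_equal(pp$high, 10000)

  # generator-truth oracle: component medians of a two-lognormal mixture
  x <- withr::with_seed(8, c(stats::rlnorm(2500, log(200), 0.3),
                             stats::rlnorm(2500, log(5000), 0.3)))
  pp2 <- detect_control_peaks(x)
  expect_lt(abs(pp2$low - stats::median(x[1:2500])) / 200, 0.02)
  expect_lt(abs(pp2$high - stats::median(x[2501:5000])) / 5000, 0.02)

  uni <- withr::with_seed(9, stats::rlnorm(2000, log(300), 0.4))
  expect_error(detect_control_peaks(uni), class = "cc_unimodal_error")
  expect_error(detect_control_peaks(x[1:100]), class = "cc_parameter_error")
})

test_that("two-point model is the unique line through the anchors", {
  m <- fit_two_point_norm(peak_pair(100, 1100), peak_pair(50, 550), "A")
  expect_equal(m$slope_ratio, 2)
  expect_equal(apply_norm(m, 550), 1100)
  expect_equal(apply_norm(m, 50), 100)

  id <- fit_two_point_norm(peak_pair(10, 500), peak_pair(10, 500))
  expect_equal(apply_norm(id, c(-5, 0, 17, 1000)), c(-5, 0, 17, 1000))

  # line-through-two-points oracle on random valid pairs
  withr::with_seed(14, {
    for (r in 1:20) {
      a <- sort(stats::runif(2, 1, 1e4)); b <- sort(stats::runif(2, 1, 1e4))
      mm <- fit_two_point_norm(peak_pair(a[1], a[2]), peak_pair(b[1], b[2]))
      slope <- (a[2] - a[1]) / (b[2] - b[1])
      intercept <- a[1] - slope * b[1]
      x <- stats::runif(100, -1e3, 1e5)
      expect_equal(apply_norm(mm, x), slope * x + intercept, tolerance = 1e-9)
    }
  })
  expect_error(fit_two_point_norm(peak_pair(1, 2),
                                  structure(list(low = 5, high = 5), class = "peak_pair")),
               class = "cc_degenerate_control_error")
})

test_that("apply_norm preserves order and scales variance by slope_ratio^2", {
  m <- fit_two_point_norm(peak_pair(100, 1100), peak_pair(50, 550))
  x <- withr::with_seed(3, sort(stats::rlnorm(2000, 5, 1)))
  y <- apply_norm(m, x)
  expect_true(all(diff(y) > 0))
  expect_equal(stats::var(y), m$slope_ratio^2 * stats::var(x), tolerance = 1e-10)
})

test_that("swapping the normalization direction composes to the identity", {
  p1 <- peak_pair(80, 9000); p2 <- peak_pair(20, 4000)
  fwd <- fit_two_point_norm(p1, p2)
  bwd <- fit_two_point_norm(p2, p1)
  x <- withr::with_seed(5, stats::rlnorm(500, 4, 1.5))
  expect_equal(apply_norm(bwd, apply_norm(fwd, x)), x, tolerance = 1e-9)
})

test_that("study normalization aligns bead anchors across days", {
  st <- generate_study(small_design(n_cells = 1500, n_beads = 1500), seed = 17)
  nr <- normalize_study(st)
  expect_identical(nrow(nr$report), 5L)
  # the distorted channel is corrected with slope ~ 1/gain
  icam <- nr$report[nr$report$channel == "ICAM1", ]
  expect_false(icam$identity)
  # after normalization the two days' bead peak statistics agree exactly
  for (d in 1:2) {
    b <- study_samples(nr$study, "bead_single_stain", day = d,
                       stain_channel = "ICAM1")[[1]]
    pp <- detect_control_peaks(b$events$values[, "ICAM1"])
    if (d == 1) ref <- pp else {
      expect_equal(pp$low, ref$low, tolerance = 1e-6)
      expect_equal(pp$high, ref$high, tolerance = 1e-6)
    }
  }
  # slope_ratio is reported for every channel (amplification caveat)
  expect_true(all(is.finite(nr$report$slope_ratio)))
})
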