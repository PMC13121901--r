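test_that("sample_population draws the requested lognormal structure", {
  p <- population_spec("p", c(A = 5000, B = 30), c(A = 0.35, B = 0.35),
                       c("5" = 1))
  expect_identical(n_events(sample_population(p, 0, seed = 1)), 0L)
  m1 <- sample_population(p, 500, seed = 3)
  m2 <- sample_population(p, 500, seed = 3)
  expect_identical(m1$values, m2$values)
  # Monte-Carlo oracle for the median of peak + autofluorescence floor
  oracle <- withr::with_seed(99, {
    stats::median(stats::rlnorm(2e5, log(5000), 0.35) +
                  stats::rlnorm(2e5, log(50), 0.5))
  })
  m <- sample_population(p, 50000, seed = 11, autofluor_location = 50,
                         autofluor_spread = 0.5)
  expect_lt(abs(stats::median(m$values[, "A"]) - oracle) / oracle, 0.02)
  expect_lt(abs(stats::median(m$values[, "A"]) - 5000) / 5000, 0.02)
  bad <- population_spec("q", c(Z = 10), c(Z = 0.1), c("5" = 1))
  expect_error(sample_population(bad, 5, seed = 1, panel = channel_panel("A")),
               class = "cc_spec_error")
})

test_that("bead samples show two sharp modes and respect batch effects", {
  d <- small_design(n_beads = 10000)
  bs <- generate_bead_sample(d, "CD31", day = 1, seed = 2)
  x <- asinh(bs$events$values[, "CD31"] / 150)
  # kernel-density oracle: exactly two modes separated by a valley
  dens <- stats::density(x)
  k <- length(dens$y)
  peaks <- which(dens$y[2:(k - 1)] > dens$y[1:(k - 2)] &
                 dens$y[2:(k - 1)] >= dens$y[3:k] &
                 dens$y[2:(k - 1)] > 0.05 * max(dens$y)) + 1
  expect_identical(length(peaks), 2L)
  # unstained channels sit at the negative-bead location
  for (ch in c("CD45", "PDPN", "VCAM1")) {
    expect_lt(abs(stats::median(bs$events$values[, ch]) -
                  d$bead_negative_location[[ch]]) / d$bead_negative_location[[ch]], 0.05)
  }
  # a day-2 gain scales the positive-peak median by that gain
  bs1 <- generate_bead_sample(d, "ICAM1", day = 1, seed = 7)
  bs2 <- generate_bead_sample(d, "ICAM1", day = 2, seed = 7)
  g <- d$batch_effects[[1]]$gain; off <- d$batch_effects[[1]]$offset
  pos1 <- stats::median(bs1$events$values[1:5000, "ICAM1"])
  pos2 <- stats::median(bs2$events$values[1:5000, "ICAM1"])
  expect_lt(abs(pos2 - (g * pos1 + off)) / (g * pos1 + off), 0.03)
  expect_error(generate_bead_sample(d, "nope", 1, seed = 1), class = "cc_spec_error")
})

test_that("generate_study produces the reference sample layout", {
  d <- small_design(n_cells = 1500, n_beads = 400)
  st <- generate_study(d, seed = 21)
  expect_length(st$samples, 14L)
  days <- vapply(st$samples, function(s) s$meta$day, integer(1))
  expect_identical(as.integer(table(days)), c(7L, 7L))
  expect_true(all(vapply(st$samples, function(s) all(is.finite(s$events$values)),
                         logical(1))))
  st2 <- generate_study(d, seed = 21)
  expect_identical(st$samples[[7]]$events$values, st2$samples[[7]]$events$values)

  # single population at proportion 1 fills the whole labeled sample
  pop <- population_spec("only", c(CD45 = 50, CD31 = 50, PDPN = 50,
                                   ICAM1 = 50, VCAM1 = 50), 0.4,
                         c("5" = 1, "12" = 1))
  d1 <- study_design(reference_panel(), list(pop), events_per_cell_sample = 300,
                     events_per_bead_sample = 250)
  st1 <- generate_study(d1, seed = 3)
  lab <- study_samples(st1 <- st1, "labeled_cells")
  lab <- Filter(function(s) s$meta$sample_type == "labeled_cells", st1$samples)
  expect_true(all(vapply(lab, function(s) all(s$truth == "only"), logical(1))))

  # proportions not summing to one are rejected
  badpop <- population_spec("half", c(CD45 = 50, CD31 = 50, PDPN = 50,
                                      ICAM1 = 50, VCAM1 = 50), 0.4, c("5" = 0.5))
  expect_error(study_design(reference_panel(), list(badpop),
                            passage_by_day = c("1" = 5)),
               class = "cc_design_error")
})

test_that("labeled-sample composition follows the passage proportions", {
  d <- reference_design(n_cells = 90000, n_beads = 300)
  st <- generate_study(d, seed = 31)
  p5 <- Filter(function(s) identical(s$meta$passage, 5L), st$samples)[[1]]
  counts <- table(p5$truth)
  props <- vapply(d$populations, function(p) p$proportion_by_passage[["5"]],
                  numeric(1))
  names(props) <- vapply(d$populations, function(p) p$name, character(1))
  for (nm in names(props)) {
    expected <- 90000 * props[[nm]]
    sd3 <- 3 * sqrt(90000 * props[[nm]] * (1 - props[[nm]]))
    expect_lt(abs(counts[[nm]] - expected), sd3 + 1)
  }
})
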