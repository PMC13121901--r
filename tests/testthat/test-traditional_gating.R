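test_that("quantile gate matches order-statistic semantics", {
  expect_equal(quantile_gate(c(5, 1, 9, 3), 1.0)$cutoff, 9)
  expect_equal(quantile_gate(as.numeric(1:1000), 0.999)$cutoff, 999)
  expect_equal(quantile_gate(list(c(1, 2, 50), c(1, 2, 80)), 1.0)$cutoff, 80)
  expect_error(quantile_gate(numeric(0), 0.999), class = "cc_parameter_error")
  # raising retention never lowers the cutoff
  x <- withr::with_seed(2, stats::rlnorm(5000, 4, 1))
  cuts <- vapply(c(0.9, 0.95, 0.995, 0.999, 1), function(r)
    quantile_gate(x, r)$cutoff, numeric(1))
  expect_true(all(diff(cuts) >= 0))
})

test_that("quadrant gates partition events, oblique matches the geometry oracle", {
  tx <- quantile_gate(c(0, 10), 1.0); ty <- quantile_gate(c(0, 10), 1.0)
  q <- quadrant_gate(c(11, 11, 5, 11), c(11, 5, 11, 11), tx, ty)
  expect_identical(as.character(q[1]), "double_pos")
  x <- withr::with_seed(3, stats::runif(500, 0, 30))
  y <- withr::with_seed(4, stats::runif(500, 0, 30))
  q2 <- quadrant_gate(x, y, tx, ty)
  expect_identical(sum(table(q2)), 500L)

  line <- list(p1 = c(0, 10), p2 = c(10, 0))
  qo <- quadrant_gate(c(2, 8), c(2, 8), tx, ty, style = "oblique", line = line)
  # signed-cross-product oracle
  cross <- function(p) (line$p2[1] - line$p1[1]) * (p[2] - line$p1[2]) -
    (line$p2[2] - line$p1[2]) * (p[1] - line$p1[1])
  expect_lt(cross(c(2, 2)), 0); expect_gt(cross(c(8, 8)), 0)
  expect_identical(as.character(qo[1]), "neg")
  expect_false(as.character(qo[2]) == "neg")
  expect_error(quadrant_gate(x, y, tx, ty, style = "oblique",
                             line = list(p1 = c(1, 1), p2 = c(1, 1))),
               class = "cc_parameter_error")
})

test_that("sequential gating recovers well-separated generator truth", {
  st <- generate_study(small_design(n_cells = 4000, n_beads = 600), seed = 12)
  st <- normalize_study(st)$study
  gr <- sequential_gating(st, gating_criteria(0.999))
  truth <- unlist(lapply(Filter(function(s) s$meta$sample_type == "labeled_cells",
                                st$samples), function(s) s$truth))
  base <- sub("_ICAM1.*", "", gr$labels)
  map <- c(hematopoietic = "CD45pos", LEC = "LEC", PvC = "PvC_DN", FRC = "FRC")
  expect_gt(mean(base == map[truth]), 0.99)
  # layer-3 sublabels partition their parent populations
  expect_identical(sum(startsWith(gr$labels, "FRC_")),
                   sum(!is.na(gr$layer2) & gr$layer2 == "FRC"))
  expect_identical(sum(table(gr$labels)), length(gr$labels))
})

test_that("autofluorescence-only labeled cells end in the double-negative path", {
  d <- small_design(n_cells = 1200, n_beads = 400)
  pop <- population_spec("af", c(CD45 = 1, CD31 = 1, PDPN = 1, ICAM1 = 1, VCAM1 = 1),
                         0.2, c("5" = 1, "12" = 1))
  d2 <- study_design(d$panel, list(pop), events_per_cell_sample = 1200,
                     events_per_bead_sample = 400)
  st <- generate_study(d2, seed = 6)
  gr <- sequential_gating(st, gating_criteria(0.999))
  expect_gt(mean(startsWith(gr$labels, "PvC_DN")), 0.99)
})

test_that("variation study computes count CVs and compounding across layers", {
  expect_equal(count_cv(c(90, 100, 110)), 10.0)
  expect_equal(count_cv(c(7, 7, 7)), 0)
  expect_true(is.na(count_cv(c(0, 0, 0))))

  st <- generate_study(small_design(n_cells = 2500, n_beads = 500,
                                    separation = "overlapping"), seed = 3)
  crit <- list(gating_criteria(0.995), gating_criteria(0.999), gating_criteria(1.0))
  vs <- gating_variation_study(st, crit)
  expect_gt(vs$mean_cv, 0)
  # identical criteria give zero CV everywhere
  vs0 <- gating_variation_study(st, list(gating_criteria(0.999), gating_criteria(0.999)))
  expect_true(all(vs0$cv[!is.na(vs0$cv)] == 0))
  expect_error(gating_variation_study(st, crit[1]), class = "cc_parameter_error")
})

test_that("gate-placement variation compounds from layer 1 to layer 3", {
  crit <- list(gating_criteria(0.995), gating_criteria(0.999), gating_criteria(1.0))
  worse <- 0
  for (sd in 1:10) {
    st <- generate_study(small_design(n_cells = 1500, n_beads = 400,
                                      separation = "overlapping"), seed = 200 + sd)
    lcv <- gating_variation_study(st, crit)$layer_mean_cv
    if (lcv[["layer3"]] > lcv[["layer1"]] && lcv[["layer3"]] > 0) worse <- worse + 1
  }
  expect_gte(worse, 8)
})
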