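test_that("expected_response follows the 4PL inhibition model", {
  p <- sprouting_model_params(D0 = 250, Imax = 1, IC50 = 20, hill = 1)
  expect_equal(expected_response(0, p), 250)
  expect_equal(expected_response(20, p), 125)  # half-maximal point
  expect_equal(expected_response(80, p), 50)   # 250 * (1 - 80/100)
  expect_error(expected_response(-1, p), "non-negative")

  # partial inhibition floors at D0 * (1 - Imax)
  pp <- sprouting_model_params(D0 = 200, Imax = 0.6, IC50 = 10, hill = 2)
  expect_equal(expected_response(1e9, pp), 200 * 0.4, tolerance = 1e-6)
})

test_that("expected_response is monotone non-increasing in concentration", {
  grid <- c(0, 10^seq(-2, 4, length.out = 40))
  for (h in c(0.5, 1, 2.5)) {
    for (imax in c(0.3, 1)) {
      p <- sprouting_model_params(D0 = 300, Imax = imax, IC50 = 15, hill = h)
      r <- expected_response(grid, p)
      expect_true(all(diff(r) <= 1e-12))
      expect_true(all(r <= p$D0 + 1e-9 & r >= p$D0 * (1 - imax) - 1e-9))
    }
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(sprouting_model_params(D0 = -1))
  expect_error(sprouting_model_params(Imax = 1.2))
  expect_error(sprouting_model_params(IC50 = 0))
  expect_error(sprouting_model_params(hill = 0))
  expect_error(sprouting_model_params(cv_chip = -0.1))
})

test_that("simulate_metric_table is exact at zero noise and errors on empty layouts", {
  lay <- control_plate_layout(n_max = 3, n_min = 3, min_conc = 50)
  p <- sprouting_model_params(cv_chip = 0, IC50 = 20, seed = 1)
  tb <- simulate_metric_table(lay, p)
  expect_equal(nrow(tb), 6)
  expect_equal(tb$distance_um[tb$role == "max_control"], rep(p$D0, 3))
  e50 <- expected_response(50, p)
  expect_equal(tb$distance_um[tb$role == "min_control"], rep(e50, 3))
  expect_error(
    simulate_metric_table(lay[0, ], p),
    "empty")
})

test_that("control-group means converge to the model expectation", {
  lay <- plate_layout("c1", "none", 0, "max_control")
  p <- sprouting_model_params(cv_chip = 0.13, seed = 7)
  tb <- simulate_metric_table(lay, p, replicates = 1e4)
  se <- p$cv_chip * p$D0 / sqrt(1e4)
  expect_lt(abs(mean(tb$distance_um) - p$D0), 3 * se)
})

test_that("group SD scales linearly with the between-chip CV", {
  lay <- plate_layout(sprintf("c%d", 1:500), "none", 0,
                      rep("max_control", 500))
  sd1 <- sd(simulate_metric_table(
    lay, sprouting_model_params(cv_chip = 0.05), seed = 3)$distance_um)
  sd2 <- sd(simulate_metric_table(
    lay, sprouting_model_params(cv_chip = 0.10), seed = 3)$distance_um)
  expect_equal(sd2 / sd1, 2, tolerance = 0.02)
})

test_that("simulation is deterministic under a fixed seed", {
  lay <- control_plate_layout(n_max = 4, n_min = 4)
  p <- sprouting_model_params()
  expect_identical(simulate_metric_table(lay, p, seed = 11),
                   simulate_metric_table(lay, p, seed = 11))
})

test_that("dose-response dataset generation enforces 4PL identifiability", {
  p <- sprouting_model_params()
  expect_error(generate_dose_response_dataset(c(0, 10, 100), p),
               "4 distinct")
  d <- generate_dose_response_dataset(c(0, 1, 10, 50, 100, 1000), p,
                                      n_per_conc = 3, seed = 5)
  expect_equal(nrow(d), 18)
  expect_setequal(d$role[d$concentration_nM == 0], "max_control")
  # saturating dose with full inhibition -> responses near zero
  psat <- sprouting_model_params(Imax = 1, IC50 = 5, cv_chip = 0.05)
  dsat <- generate_dose_response_dataset(c(0, 1, 10, 1e6), psat,
                                         n_per_conc = 4, seed = 6)
  expect_lt(max(dsat$distance_um[dsat$concentration_nM == 1e6]),
            0.01 * psat$D0)
})

test_that("rendering is deterministic and respects the sprout count", {
  p <- tiny_params(seed = 4)
  g <- tiny_geometry()
  r1 <- render_chip_stack(p, g, seed = 4)
  r2 <- render_chip_stack(p, g, seed = 4)
  expect_identical(r1$stack$channels, r2$stack$channels)
  expect_identical(r1$truth$nuclei, r2$truth$nuclei)

  # no sprouts: the gel region of the F-actin channel is background only
  p0 <- tiny_params(sprouts_per_chip = 0, seed = 8)
  r0 <- render_chip_stack(p0, g, seed = 8, noise = FALSE)
  gel_rows <- (ceiling(p0$baseline_y / g$pixel_size) + 2):g$height_px
  expect_equal(max(r0$stack$channels$factin[gel_rows, , ]), 0)
  expect_equal(r0$truth$true_nuclei_in_sprouts, 0)
})

test_that("rendered nuclei in the gel region are recovered by segmentation", {
  p <- tiny_params(seed = 21)
  r <- render_chip_stack(p, tiny_geometry(), seed = 21)
  det <- segment_nuclei(max_project(r$stack)$channels$nuclei,
                        pixel_size = r$stack$pixel_size)
  truth_gel <- r$truth$nuclei[r$truth$nuclei$y > p$baseline_y, ]
  det_gel <- det[det$y > p$baseline_y, ]
  m <- match_centroids(truth_gel, det_gel, tol_um = 5)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
})

test_that("render-segment-quantify round trip recovers the true distance", {
  p <- tiny_params(seed = 31)
  r <- render_chip_stack(p, tiny_geometry(), seed = 31, noise = FALSE)
  seg <- segment_projection(max_project(r$stack), baseline_y = p$baseline_y)
  m <- quantify_chip(seg, "rt")
  expect_lt(abs(m$distance_um - r$truth$true_distance),
            2 * p$nuclei_spacing)
})
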