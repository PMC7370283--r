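# build a segmentation_result by hand without running any image code
make_seg <- function(mask, nuclei, baseline_y, pixel_size = 1) {
  structure(list(vessel_mask = mask, skeleton = skeletonize(mask),
                 nuclei = nuclei, baseline_y = baseline_y,
                 pixel_size = pixel_size),
            class = "segmentation_result")
}

test_that("migration distance averages the k furthest nuclei past the baseline", {
  # 12 nuclei at 400, 410, ..., 510; strictly beyond 400 leaves 11,
  # top-10 are 420..510 with mean 465
  nuc <- data.frame(x = seq(0, 110, 10), y = seq(400, 510, 10))
  expect_equal(migration_distance(nuc, baseline_y = 400, k = 10), 65)
  # fewer than k eligible: average them all
  expect_equal(migration_distance(data.frame(x = 1:3, y = c(450, 500, 600)),
                                  400),
               mean(c(450, 500, 600)) - 400, tolerance = 1e-10)
  # nobody past the baseline: complete inhibition maps to 0
  expect_equal(migration_distance(data.frame(x = 1, y = 350), 400), 0)
  expect_equal(migration_distance(data.frame(x = numeric(0),
                                             y = numeric(0)), 400), 0)
})

test_that("migration distance matches a brute-force oracle on random sets", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(0:40, 1)
    y <- round(runif(n, 0, 800), 1)
    x <- runif(n, 0, 500)
    k <- sample(1:12, 1)
    base <- sample(c(0, 200, 400), 1)
    oracle <- {
      yy <- sort(y[y > base], decreasing = TRUE)
      if (length(yy) == 0) 0 else mean(yy[seq_len(min(k, length(yy)))]) - base
    }
    expect_equal(migration_distance(data.frame(x = x, y = y), base, k),
                 oracle)
  }
})

test_that("sprout area counts only nuclei-containing components past the baseline", {
  mask <- matrix(FALSE, 60, 60)
  mask[30:49, 5:29] <- TRUE    # 500 px component
  mask[30:44, 40:59] <- TRUE   # 300 px component
  nuc <- data.frame(x = c(10, 20, 50) * 0.677, y = c(35, 40, 20) * 0.677)
  # baseline at 15 px: both components beyond it; only the 500 px one
  # holds nuclei (the third nucleus falls on background pixels)
  seg <- make_seg(mask, nuc, baseline_y = 15 * 0.677, pixel_size = 0.677)
  expect_equal(total_sprout_area(seg), 500 * 0.677^2)
  # empty mask
  seg0 <- make_seg(matrix(FALSE, 60, 60), nuc, 10, 0.677)
  expect_equal(total_sprout_area(seg0), 0)
  # every component populated: gate is vacuous, area = full mask area
  nuc2 <- data.frame(x = c(10, 50) * 0.677, y = c(35, 35) * 0.677)
  seg2 <- make_seg(mask, nuc2, baseline_y = 15 * 0.677, pixel_size = 0.677)
  expect_equal(total_sprout_area(seg2), 800 * 0.677^2)
  # gated area never exceeds the mask area beyond the baseline
  expect_lte(total_sprout_area(seg), sum(mask[16:60, ]) * 0.677^2)
})

test_that("nuclei_in_sprouts gates on baseline and vessel mask", {
  mask <- matrix(FALSE, 50, 50)
  mask[1:40, 20:30] <- TRUE
  nuc <- data.frame(x = c(25, 25, 25, 25, 25, 25, 25, 25, 5, 45, 25),
                    y = c(31, 33, 35, 37, 39, 5, 10, 15, 35, 35, 45))
  seg <- make_seg(mask, nuc, baseline_y = 30, pixel_size = 1)
  # 5 inside the mask beyond y=30; 3 in the monolayer; 2 outside the
  # mask; 1 beyond the mask extent in y
  expect_equal(nuclei_in_sprouts(seg), 5L)
  expect_equal(nuclei_in_sprouts(make_seg(mask, nuc[0, ], 30)), 0L)
})

test_that("metrics are invariant to x-translation of the segmentation", {
  mask <- matrix(FALSE, 60, 80)
  mask[20:50, 10:20] <- TRUE
  nuc <- data.frame(x = c(15, 15), y = c(30, 45))
  seg <- make_seg(mask, nuc, baseline_y = 10, pixel_size = 1)
  shifted_mask <- matrix(FALSE, 60, 80)
  shifted_mask[20:50, 40:50] <- TRUE
  seg2 <- make_seg(shifted_mask, transform(nuc, x = x + 30), 10, 1)
  expect_equal(total_sprout_area(seg2), total_sprout_area(seg))
  expect_equal(nuclei_in_sprouts(seg2), nuclei_in_sprouts(seg))
  expect_equal(total_vessel_length(seg2), total_vessel_length(seg))
  expect_equal(migration_distance(seg2$nuclei, 10),
               migration_distance(seg$nuclei, 10))
})

test_that("quantify_chip averages distance and sums extensive readouts", {
  mask <- matrix(FALSE, 60, 60)
  mask[20:50, 10:30] <- TRUE
  nuc <- data.frame(x = rep(20, 4), y = c(25, 30, 40, 50))
  seg <- make_seg(mask, nuc, baseline_y = 15, pixel_size = 1)
  one <- quantify_chip(seg, "solo")
  expect_equal(one$n_sites, 1)
  two <- quantify_chip(list(seg, seg), "dup")
  expect_equal(two$distance_um, one$distance_um)
  expect_equal(two$total_area_um2, 2 * one$total_area_um2)
  expect_equal(two$nuclei_count, 2 * one$nuclei_count)
  expect_equal(two$length_um, 2 * one$length_um)
  seg_other <- make_seg(mask, nuc, baseline_y = 15, pixel_size = 2)
  expect_error(quantify_chip(list(seg, seg_other)), "pixel sizes")
})
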