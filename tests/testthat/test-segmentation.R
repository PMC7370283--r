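test_that("blank images yield no nuclei and an empty vessel mask", {
  blank <- matrix(0, 50, 50)
  expect_equal(nrow(segment_nuclei(blank, 2.7)), 0)
  expect_false(any(segment_vessel_mask(blank, 2.7)))
})

test_that("two well-separated blobs give two centroids within one pixel", {
  ps <- 2.7
  centers <- cbind(x = c(80, 220), y = c(100, 180))
  img <- blob_image(centers, dims = c(120, 120), pixel_size = ps)
  det <- segment_nuclei(img, ps)
  expect_equal(nrow(det), 2)
  ord <- order(det$x)
  expect_lt(max(abs(det$x[ord] - centers[, "x"])), ps)
  expect_lt(max(abs(det$y[ord] - centers[, "y"])), ps)
})

test_that("nuclei detection is translation-equivariant", {
  ps <- 2.7
  centers <- cbind(x = c(70, 150, 230), y = c(90, 160, 240))
  d0 <- segment_nuclei(blob_image(centers, dims = c(140, 140)), ps)
  shift_px <- c(dy = 7, dx = -5)
  shifted <- centers + ps * cbind(rep(shift_px["dx"], 3), rep(shift_px["dy"], 3))
  d1 <- segment_nuclei(blob_image(shifted, dims = c(140, 140)), ps)
  expect_equal(nrow(d1), 3)
  expect_equal(d1$x[order(d1$x)], d0$x[order(d0$x)] + ps * shift_px[["dx"]],
               tolerance = ps)
  expect_equal(d1$y[order(d1$y)], d0$y[order(d0$y)] + ps * shift_px[["dy"]],
               tolerance = ps)
})

test_that("a 20 um x 200 um tube is segmented with close to its nominal area", {
  ps <- 2.7
  img <- tube_image(x0 = 200, y0 = 100, y1 = 300, width_um = 20,
                    dims = c(160, 160), pixel_size = ps)
  mask <- segment_vessel_mask(img, ps)
  area <- sum(mask) * ps^2
  expect_lt(abs(area - 4000), 0.2 * 4000)
})

test_that("the vessel mask covers the rendered sprout paths", {
  p <- tiny_params(seed = 17)
  r <- render_chip_stack(p, tiny_geometry(), seed = 17, noise = FALSE)
  proj <- max_project(r$stack)
  mask <- segment_vessel_mask(proj$channels$factin, proj$pixel_size)
  # ground-truth sprout pixels: within half a width of any polyline vertex
  ps <- proj$pixel_size
  pts <- do.call(rbind, lapply(r$truth$sprout_paths, function(m) m))
  pts <- pts[pts[, "y"] > p$baseline_y, , drop = FALSE]
  rr <- pmin(pmax(ceiling(pts[, "y"] / ps), 1), nrow(mask))
  cc <- pmin(pmax(ceiling(pts[, "x"] / ps), 1), ncol(mask))
  expect_gte(mean(mask[cbind(rr, cc)]), 0.95)
})

test_that("mask area does not decrease when a structure is added", {
  ps <- 2.7
  one <- tube_image(100, 50, 350, dims = c(160, 160))
  two <- one + tube_image(300, 50, 350, dims = c(160, 160))
  expect_gte(sum(segment_vessel_mask(two, ps)),
             sum(segment_vessel_mask(one, ps)))
})

test_that("skeleton length counts orthogonal and diagonal steps correctly", {
  m <- matrix(FALSE, 120, 120)
  expect_equal(skeleton_length(m, 1), 0)
  h <- m; h[60, 10:110] <- TRUE            # 101 px horizontal line
  expect_equal(skeleton_length(h, 1), 100)
  d <- m; d[cbind(10:110, 10:110)] <- TRUE # 101 px diagonal line
  expect_equal(skeleton_length(d, 1), 100 * sqrt(2))
  expect_equal(skeleton_length(h, 0.677), 100 * 0.677)
})

test_that("the skeleton is a thin subset of the mask, stable under dilation", {
  ps <- 2.7
  img <- tube_image(200, 60, 380, dims = c(160, 160))
  mask <- segment_vessel_mask(img, ps)
  sk <- skeletonize(mask)
  expect_true(all(mask[sk]))  # skeleton subset of mask
  l0 <- skeleton_length(mask, ps)
  dil <- EBImage::dilate(mask, EBImage::makeBrush(3, "box")) > 0
  expect_lt(abs(skeleton_length(dil, ps) - l0) / l0, 0.10)
})

test_that("segment_projection bundles channels and enforces their presence", {
  p <- tiny_params(seed = 12)
  r <- render_chip_stack(p, tiny_geometry(), seed = 12)
  proj <- max_project(r$stack)
  seg <- segment_projection(proj, baseline_y = p$baseline_y)
  expect_s3_class(seg, "segmentation_result")
  expect_true(all(seg$vessel_mask[seg$skeleton]))
  expect_true(all(seg$nuclei$x >= 0 &
                    seg$nuclei$x <= ncol(seg$vessel_mask) * seg$pixel_size))
  bad <- projected_image(list(nuclei = proj$channels$nuclei), proj$pixel_size)
  expect_error(segment_projection(bad), "factin")
})
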