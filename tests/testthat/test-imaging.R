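test_that("stack write/read round trip preserves voxels and metadata", {
  p <- tiny_params(sprouts_per_chip = 3, seed = 3)
  r <- render_chip_stack(p, chip_geometry(96, 96, 5, 2.7, 1), seed = 3)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(r$stack, tf)
  s2 <- read_stack(tf)
  expect_equal(s2$channels$nuclei, r$stack$channels$nuclei,
               ignore_attr = TRUE)
  expect_equal(s2$channels$factin, r$stack$channels$factin,
               ignore_attr = TRUE)
  expect_equal(s2$pixel_size, 2.7)
  expect_equal(s2$z_step, 1)
  expect_equal(names(s2$channels), c("nuclei", "factin"))
})

test_that("single-plane TIFFs load as degenerate stacks", {
  img <- matrix(as.integer(seq(0, 65535, length.out = 64)), 8, 8)
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img / 65535, tf, bits.per.sample = 16L,
                  compression = "none")
  s <- read_stack(tf, channels = "nuclei", pixel_size = 0.677)
  expect_equal(dim(s$channels$nuclei), c(8, 8, 1))
  expect_equal(s$pixel_size, 0.677)
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "no such file")
})

test_that("an 80-plane two-channel stack round trips with its 1 um z-step", {
  ch <- list(
    nuclei = array(sample.int(65536, 24 * 24 * 80, TRUE) - 1L,
                   dim = c(24, 24, 80)),
    factin = array(0, dim = c(24, 24, 80)))
  st <- chip_stack(ch, pixel_size = 0.677, z_step = 1)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, tf)
  s2 <- read_stack(tf)
  expect_equal(dim(s2$channels$nuclei)[3], 80)
  expect_equal(s2$z_step, 1)
  expect_equal(s2$channels$nuclei, ch$nuclei, ignore_attr = TRUE)
})

test_that("max projection takes the per-pixel maximum over z", {
  const <- chip_stack(list(nuclei = array(7, c(4, 5, 3))), 1)
  expect_equal(max_project(const)$channels$nuclei, matrix(7, 4, 5))

  a <- array(0, c(6, 6, 4)); a[2, 3, 2] <- 100
  pr <- max_project(chip_stack(list(nuclei = a), 1))$channels$nuclei
  expect_equal(pr[2, 3], 100)
  expect_equal(sum(pr), 100)

  set.seed(2)
  rnd <- array(runif(5 * 5 * 6), c(5, 5, 6))
  prj <- max_project(chip_stack(list(nuclei = rnd), 1))$channels$nuclei
  for (z in 1:6) expect_true(all(prj >= rnd[, , z]))

  # idempotent on a single-plane stack
  one <- chip_stack(list(nuclei = array(rnd[, , 1], c(5, 5, 1))), 1)
  expect_equal(max_project(one)$channels$nuclei, rnd[, , 1],
               ignore_attr = TRUE)
})

test_that("stitching recovers the true translation of overlapping sites", {
  p <- sprouting_model_params(seed = 9)
  r <- render_chip_stack(p, chip_geometry(height_px = 640, width_px = 256),
                         seed = 9)
  master <- max_project(r$stack)
  h <- 320; ov <- 0.1
  cut <- function(r0) {
    projected_image(lapply(master$channels, function(m) {
      m[r0:(r0 + h - 1), ]
    }), master$pixel_size)
  }
  A <- cut(1)
  for (true_dy in c(288, 290, 285)) {  # nominal is round(320 * 0.9) = 288
    B <- cut(true_dy + 1)
    st <- stitch_pair(A, B, nominal_overlap = ov)
    expect_equal(nrow(st$channels$nuclei), true_dy + h)  # exact dy recovery
    expect_lt(mean(abs(st$channels$factin -
                         master$channels$factin[1:(true_dy + h), ])), 1)
  }
})

test_that("blend weights ramp 0 to 1 across the seam and sum to 1", {
  A <- projected_image(list(nuclei = matrix(1, 40, 20)), 1)
  B <- projected_image(list(nuclei = matrix(0, 40, 20)), 1)
  st <- suppressWarnings(stitch_pair(A, B, nominal_overlap = 0.25))
  fused <- st$channels$nuclei  # fused value = weight of A since B = 0
  dy <- 30  # round(40 * 0.75)
  expect_equal(fused[dy, 1], 1)       # last A-only row
  expect_equal(fused[dy + 1, 1], 1)   # A-side overlap edge: weight 1
  expect_equal(fused[40, 1], 0)       # B-side overlap edge: weight 0
  ovl <- fused[(dy + 1):40, 1]
  expect_true(all(diff(ovl) < 0))     # linear monotone ramp
  expect_true(all(ovl >= 0 & ovl <= 1))
})

test_that("implausible correlation peaks fall back to the nominal offset", {
  set.seed(13)
  base <- matrix(runif(60 * 30), 60, 30)
  A <- projected_image(list(nuclei = base), 1)
  # B is A shifted by half a frame: true peak far from the nominal 10%
  B <- projected_image(list(nuclei = base[c(31:60, 1:30), ]), 1)
  expect_warning(st <- stitch_pair(A, B, nominal_overlap = 0.1),
                 "falling back to nominal")
  expect_equal(nrow(st$channels$nuclei), 54 + 60)
  expect_error(stitch_pair(A, B, nominal_overlap = 0.8), "0.5")
  Bps <- projected_image(list(nuclei = base), 2)
  expect_error(stitch_pair(A, Bps), "pixel sizes")
})
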