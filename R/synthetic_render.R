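#' Synthetic chip acquisition geometry
#'
#' Frame geometry for rendered chips. The default is a 512 x 512 px
#' field at 2.7 um/px with 8 z-planes at 5 um: the same physical field
#' of view as a full-resolution acquisition (2048 x 2048 at 0.677 um/px,
#' 80 z-planes at 1 um, available via `chip_geometry(2048, 2048, 80,
#' 0.677, 1)`) but coarse enough that a full render-segment-quantify
#' cycle runs in seconds.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param n_z Number of z-planes.
#' @param pixel_size Lateral pixel size, um/px.
#' @param z_step Axial step, um.
#' @param bit_depth Bits per sample.
#' @param gel_window Depth of the gel region beyond the baseline that
#'   sprouts may occupy, um.
#' @return An object of class `chip_geometry`.
#' @export
chip_geometry <- function(width_px = 512, height_px = 512, n_z = 8,
                          pixel_size = 2.7, z_step = 5, bit_depth = 16,
                          gel_window = 500) {
  stopifnot(width_px > 0, height_px > 0, n_z >= 1, pixel_size > 0,
            z_step > 0, gel_window > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), n_z = as.integer(n_z),
                 pixel_size = pixel_size, z_step = z_step,
                 bit_depth = as.integer(bit_depth),
                 gel_window = gel_window),
            class = "chip_geometry")
}

# rendering intensity model (16-bit counts)
.render_levels <- list(
  nucleus_amp = 9000, nucleus_sigma_um = 4, nucleus_sigma_z = 1.2,
  tube_amp = 4000, monolayer_factin = 3000,
  background = 100, read_noise_sd = 20
)

#' Sample the ground truth of one synthetic chip
#'
#' Draws the latent state of a chip at a given inhibitor concentration:
#' sprout polylines extending from the monolayer baseline into the gel
#' (lengths set by the 4PL dose response plus between-chip and
#' between-sprout noise), nuclei spaced along each sprout, and a dense
#' band of monolayer nuclei behind the baseline. The returned record is
#' the oracle against which segmentation and metrics are validated.
#'
#' @param params A [sprouting_model_params()].
#' @param geometry A [chip_geometry()].
#' @param concentration Inhibitor concentration (units of `params$IC50`).
#' @return An object of class `chip_ground_truth`: list with
#'   `nuclei` (data.frame x, y, z um, logical `in_sprout`),
#'   `sprout_paths` (list of x/y matrices, um), `true_distance` (um),
#'   `true_area` (um^2), `true_nuclei_in_sprouts`, `baseline_y`,
#'   `concentration`.
#' @export
sample_chip_truth <- function(params, geometry = chip_geometry(),
                              concentration = 0) {
  stopifnot(inherits(params, "sprouting_model_params"),
            inherits(geometry, "chip_geometry"))
  wu <- geometry$width_px * geometry$pixel_size
  hu <- geometry$height_px * geometry$pixel_size
  zu <- geometry$n_z * geometry$z_step
  base <- params$baseline_y
  if (base >= hu) stop("baseline_y lies beyond the frame height")
  max_len <- min(geometry$gel_window, hu - base - 2 * geometry$pixel_size)

  e_dist <- expected_response(concentration, params)
  chip_dist <- .rtrunc0(1, e_dist, params$cv_chip * e_dist)

  step <- params$nuclei_spacing
  n_spr <- params$sprouts_per_chip
  paths <- list()
  spr_nuc <- NULL
  if (n_spr > 0) {
    margin <- 0.05 * wu
    x0 <- seq(margin, wu - margin, length.out = n_spr) +
      stats::rnorm(n_spr, 0, step / 4)
    x0 <- pmin(pmax(x0, 2 * geometry$pixel_size), wu - 2 * geometry$pixel_size)
    lens <- pmin(.rtrunc0(n_spr, rep(chip_dist, n_spr),
                          rep(0.10 * max(chip_dist, 1e-6), n_spr)), max_len)
    for (s in seq_len(n_spr)) {
      n_seg <- floor(lens[s] / step)
      if (n_seg < 1) { paths[[s]] <- cbind(x = x0[s], y = base); next }
      xs <- x0[s] + cumsum(c(0, stats::rnorm(n_seg, 0, step / 6)))
      xs <- pmin(pmax(xs, 2 * geometry$pixel_size),
                 wu - 2 * geometry$pixel_size)
      ys <- base + step * (0:n_seg)
      paths[[s]] <- cbind(x = xs, y = ys)
      zc <- zu / 2 + stats::rnorm(n_seg, 0, geometry$z_step / 2)
      spr_nuc <- rbind(spr_nuc, data.frame(
        x = xs[-1], y = ys[-1], z = pmin(pmax(zc, 0), zu),
        in_sprout = TRUE))
    }
  }

  # monolayer nuclei: jittered grid band behind the baseline
  band <- 80
  gx <- seq(step / 2, wu - step / 2, by = step)
  gy <- seq(max(step / 2, base - band), base - step / 4, by = step * 0.9)
  grid <- expand.grid(x = gx, y = gy)
  mono <- data.frame(
    x = pmin(pmax(grid$x + stats::rnorm(nrow(grid), 0, step / 5), 1), wu - 1),
    y = pmin(pmax(grid$y + stats::rnorm(nrow(grid), 0, step / 5), 1),
             base - 1),
    z = zu / 2 + stats::rnorm(nrow(grid), 0, geometry$z_step / 2),
    in_sprout = FALSE)
  mono$z <- pmin(pmax(mono$z, 0), zu)

  nuclei <- rbind(spr_nuc, mono)
  sy <- nuclei$y[nuclei$in_sprout & nuclei$y > base]
  true_dist <- if (length(sy) == 0) 0 else {
    k <- min(10L, length(sy))
    mean(sort(sy, decreasing = TRUE)[seq_len(k)]) - base
  }
  seg_len <- vapply(paths, function(p) {
    if (nrow(p) < 2) 0 else sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  }, 0)
  structure(list(
    nuclei = nuclei, sprout_paths = paths,
    true_distance = true_dist,
    true_area = sum(seg_len) * params$sprout_width,
    true_nuclei_in_sprouts = sum(nuclei$in_sprout & nuclei$y > base),
    baseline_y = base, concentration = concentration),
    class = "chip_ground_truth")
}

# add a Gaussian-profile tube along segment p1->p2 (um) to a 2D image
.add_tube <- function(img, p1, p2, sigma_um, amp, ps) {
  pad <- ceiling(3 * sigma_um / ps)
  r1 <- max(1L, floor(min(p1[2], p2[2]) / ps) - pad)
  r2 <- min(nrow(img), ceiling(max(p1[2], p2[2]) / ps) + pad)
  c1 <- max(1L, floor(min(p1[1], p2[1]) / ps) - pad)
  c2 <- min(ncol(img), ceiling(max(p1[1], p2[1]) / ps) + pad)
  if (r1 > r2 || c1 > c2) return(img)
  ys <- ((r1:r2) - 0.5) * ps
  xs <- ((c1:c2) - 0.5) * ps
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx^2 + vy^2
  t <- if (l2 == 0) 0 else
    pmin(pmax(((px - p1[1]) * vx + (py - p1[2]) * vy) / l2, 0), 1)
  d2 <- (px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2
  img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] + amp * exp(-d2 / (2 * sigma_um^2))
  img
}

#' Render a synthetic two-channel chip stack
#'
#' Renders the ground truth sampled by [sample_chip_truth()] into a
#' two-channel 16-bit stack: the F-actin channel is a uniform monolayer
#' band behind the baseline plus Gaussian-profile tubes along each
#' sprout polyline (spread over z with a Gaussian axial profile); the
#' nuclei channel is a sum of 3D Gaussian blobs, one per nucleus. With
#' `noise = TRUE` (default), per-voxel Poisson photon noise, a constant
#' background offset and Gaussian read noise are applied before rounding
#' to integer counts. Rendering is deterministic given `seed`.
#'
#' @param params A [sprouting_model_params()].
#' @param geometry A [chip_geometry()].
#' @param concentration Inhibitor concentration for the dose-dependent
#'   sprout extent.
#' @param seed Optional integer seed (defaults to `params$seed`).
#' @param noise Apply the Poisson + read-noise model.
#' @param truth Optionally, a pre-sampled [sample_chip_truth()] record
#'   to render; when `NULL` a new one is drawn.
#' @return A list with elements `stack` ([chip_stack()]) and `truth`
#'   ([sample_chip_truth()] record).
#' @export
render_chip_stack <- function(params, geometry = chip_geometry(),
                              concentration = 0, seed = params$seed,
                              noise = TRUE, truth = NULL) {
  stopifnot(inherits(geometry, "chip_geometry"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) {
    truth <- sample_chip_truth(params, geometry, concentration)
  }
  lv <- .render_levels
  ps <- geometry$pixel_size
  h <- geometry$height_px; w <- geometry$width_px; nz <- geometry$n_z
  zu <- nz * geometry$z_step
  vmax <- 2^geometry$bit_depth - 1

  nuc <- truth$nuclei
  outside <- nuc$x < 0 | nuc$x > w * ps | nuc$y < 0 | nuc$y > h * ps
  if (any(outside)) {
    warning(sum(outside), " nuclei outside the frame were clipped")
    nuc$x <- pmin(pmax(nuc$x, 0), w * ps)
    nuc$y <- pmin(pmax(nuc$y, 0), h * ps)
  }

  # F-actin: 2D template spread over z with a Gaussian axial profile
  fact2d <- matrix(0, h, w)
  base_rows <- seq_len(max(0L, min(h, floor(truth$baseline_y / ps))))
  fact2d[base_rows, ] <- lv$monolayer_factin
  sig_tube <- params$sprout_width / 2.5
  for (p in truth$sprout_paths) {
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      fact2d <- .add_tube(fact2d, p[i, ], p[i + 1, ], sig_tube,
                          lv$tube_amp, ps)
    }
  }
  zc <- (seq_len(nz) - 0.5) * geometry$z_step
  zprof <- exp(-(zc - zu / 2)^2 / (2 * (zu / 4)^2))
  factin <- array(0, dim = c(h, w, nz))
  for (z in seq_len(nz)) factin[, , z] <- fact2d * zprof[z]

  # nuclei: 3D Gaussian blobs
  nuc3d <- array(0, dim = c(h, w, nz))
  sxy <- lv$nucleus_sigma_um
  szz <- lv$nucleus_sigma_z * geometry$z_step
  pad <- ceiling(3 * sxy / ps)
  for (i in seq_len(nrow(nuc))) {
    rc <- nuc$y[i] / ps + 0.5; cc <- nuc$x[i] / ps + 0.5
    r1 <- max(1L, floor(rc - pad)); r2 <- min(h, ceiling(rc + pad))
    c1 <- max(1L, floor(cc - pad)); c2 <- min(w, ceiling(cc + pad))
    if (r1 > r2 || c1 > c2) next
    gy <- exp(-(((r1:r2) - 0.5) * ps - nuc$y[i])^2 / (2 * sxy^2))
    gx <- exp(-(((c1:c2) - 0.5) * ps - nuc$x[i])^2 / (2 * sxy^2))
    gz <- exp(-(zc - nuc$z[i])^2 / (2 * szz^2))
    blob <- outer(gy, gx)
    for (z in seq_len(nz)) {
      if (gz[z] < 1e-4) next
      nuc3d[r1:r2, c1:c2, z] <- nuc3d[r1:r2, c1:c2, z] +
        lv$nucleus_amp * gz[z] * blob
    }
  }

  channels <- list(nuclei = nuc3d, factin = factin)
  if (noise) {
    channels <- lapply(channels, function(a) {
      n <- length(a)
      noisy <- stats::rpois(n, as.vector(a) + lv$background) +
        stats::rnorm(n, 0, lv$read_noise_sd)
      array(pmin(pmax(round(noisy), 0), vmax), dim = dim(a))
    })
  } else {
    channels <- lapply(channels, function(a) {
      array(pmin(round(a), vmax), dim = dim(a))
    })
  }
  list(stack = chip_stack(channels, pixel_size = ps,
                          z_step = geometry$z_step,
                          bit_depth = geometry$bit_depth),
       truth = truth)
}
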