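# small-frame fixtures: same physics as the defaults, desk-scale frames

tiny_geometry <- function(...) {
  chip_geometry(width_px = 160, height_px = 160, n_z = 4, pixel_size = 2.7,
                z_step = 5, ...)
}

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(D0 = 150, baseline_y = 100, sprouts_per_chip = 5), list(...))
  do.call(sprouting_model_params, args)
}

# image with Gaussian blobs at the given centres (um)
blob_image <- function(centers, dims = c(120, 120), pixel_size = 2.7,
                       sigma_um = 4, amp = 5000) {
  img <- matrix(0, dims[1], dims[2])
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * outer(
      exp(-(ys - centers[i, 2])^2 / (2 * sigma_um^2)),
      exp(-(xs - centers[i, 1])^2 / (2 * sigma_um^2)))
  }
  img
}

# vertical Gaussian-profile tube centred at x0, spanning [y0, y1] (um)
tube_image <- function(x0, y0, y1, width_um = 20, dims = c(160, 160),
                       pixel_size = 2.7, amp = 5000) {
  img <- matrix(0, dims[1], dims[2])
  sigma <- width_um / 2.5
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  prof_x <- exp(-(xs - x0)^2 / (2 * sigma^2))
  in_y <- as.numeric(ys >= y0 & ys <= y1)
  img + amp * outer(in_y, prof_x)
}

# recall / precision of detected centroids against ground truth, um
match_centroids <- function(truth, detected, tol_um = 5) {
  if (nrow(truth) == 0 || nrow(detected) == 0) {
    return(list(recall = 0, precision = 0))
  }
  d2 <- outer(truth$x, detected$x, "-")^2 + outer(truth$y, detected$y, "-")^2
  list(recall = mean(apply(d2, 1, min) <= tol_um^2),
       precision = mean(apply(d2, 2, min) <= tol_um^2))
}

# independent textbook implementations of the guard-banded statistics
bf_signal_window <- function(am, sm, nm, ai, si, ni) {
  ((am - 3 * sm / sqrt(nm)) - (ai + 3 * si / sqrt(ni))) / (sm / sqrt(nm))
}
bf_z_factor <- function(am, sm, nm, ai, si, ni) {
  ((am - 3 * sm / sqrt(nm)) - (ai + 3 * si / sqrt(ni))) / (am - ai)
}

# published per-readout performance figures used for consistency checks
published_perf <- list(
  area = list(sw = 11.70, z = 0.78, avr = 0.84, cv_max = 0.25, cv_min = 0.70),
  distance = list(sw = 14.76, z = 0.75, avr = 0.94, cv_max = 0.13,
                  cv_min = 0.20),
  nuclei = list(sw = 11.68, z = 0.77, avr = 0.88, cv_max = 0.24,
                cv_min = 0.71))
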