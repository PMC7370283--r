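#' Migration distance of the furthest nuclei
#'
#' The sprouting-distance readout: the mean y-position of the `k`
#' furthest nuclei beyond the baseline, minus the baseline (default 400
#' um, the average position where the monolayer abuts the gel). Only
#' nuclei with `y > baseline_y` are eligible. When fewer than `k` (but
#' at least one) nuclei are eligible their mean is used; with none the
#' distance is 0, so a completely inhibited chip maps to the assay's
#' minimum signal rather than to a missing value. Ties at the k-th
#' y-value are broken deterministically by (y, then x) ordering.
#'
#' @param nuclei `data.frame` with columns `x`, `y` (um), or a numeric
#'   vector of y-positions.
#' @param baseline_y Baseline position, um (>= 0).
#' @param k Number of furthest nuclei to average (default 10).
#' @return Migration distance, um (>= 0).
#' @examples
#' migration_distance(data.frame(x = 0, y = seq(400, 510, 10)), 400)
#' @export
migration_distance <- function(nuclei, baseline_y = 400, k = 10) {
  stopifnot(baseline_y >= 0, k >= 1)
  if (is.data.frame(nuclei)) {
    y <- nuclei$y
    x <- if (!is.null(nuclei$x)) nuclei$x else rep(0, length(y))
  } else {
    y <- as.numeric(nuclei)
    x <- rep(0, length(y))
  }
  keep <- y > baseline_y
  y <- y[keep]; x <- x[keep]
  if (length(y) == 0L) return(0)
  ord <- order(-y, x)
  top <- y[ord][seq_len(min(k, length(y)))]
  max(mean(top) - baseline_y, 0)
}

# label the vessel mask restricted to the gel region (y > baseline)
.sprout_components <- function(seg) {
  ps <- seg$pixel_size
  mask <- seg$vessel_mask
  base_row <- floor(seg$baseline_y / ps)  # rows <= base_row have y <= baseline
  if (base_row >= 1) {
    mask[seq_len(min(base_row, nrow(mask))), ] <- FALSE
  }
  EBImage::imageData(EBImage::bwlabel(mask))
}

# map nucleus centroids (um) to matrix indices, NA when outside
.nuclei_pixels <- function(nuclei, ps, dims) {
  r <- ceiling(nuclei$y / ps); c <- ceiling(nuclei$x / ps)
  r[r < 1 | r > dims[1]] <- NA; c[c < 1 | c > dims[2]] <- NA
  cbind(r, c)
}

#' Total sprout area, gated by nuclei
#'
#' Area of the vessel mask beyond the baseline, counting only connected
#' components that contain at least one nucleus centroid — sprout-like
#' F-actin structures without a nucleus (debris, matrix texture) are
#' excluded.
#'
#' @param seg A [segment_projection()] result.
#' @return Area in um^2.
#' @export
total_sprout_area <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  lab <- .sprout_components(seg)
  if (!any(lab > 0)) return(0)
  area_px <- tabulate(lab[lab > 0])
  nuc <- seg$nuclei[seg$nuclei$y > seg$baseline_y, , drop = FALSE]
  if (nrow(nuc) == 0L) return(0)
  rc <- .nuclei_pixels(nuc, seg$pixel_size, dim(lab))
  ok <- stats::complete.cases(rc)
  hit <- unique(lab[rc[ok, , drop = FALSE]])
  hit <- hit[hit > 0]
  sum(area_px[hit]) * seg$pixel_size^2
}

#' Number of nuclei within the sprouts
#'
#' Counts nucleus centroids beyond the baseline that fall inside the
#' vessel mask.
#'
#' @param seg A [segment_projection()] result.
#' @return Integer count.
#' @export
nuclei_in_sprouts <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  nuc <- seg$nuclei[seg$nuclei$y > seg$baseline_y, , drop = FALSE]
  if (nrow(nuc) == 0L) return(0L)
  rc <- .nuclei_pixels(nuc, seg$pixel_size, dim(seg$vessel_mask))
  ok <- stats::complete.cases(rc)
  sum(seg$vessel_mask[rc[ok, , drop = FALSE]])
}

#' Total vessel length beyond the baseline
#'
#' Sums the skeleton length ([skeleton_length()]) of the stored
#' skeleton restricted to `y > baseline_y`.
#'
#' @param seg A [segment_projection()] result.
#' @return Length in um.
#' @export
total_vessel_length <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  sk <- seg$skeleton
  base_row <- floor(seg$baseline_y / seg$pixel_size)
  if (base_row >= 1) sk[seq_len(min(base_row, nrow(sk))), ] <- FALSE
  skeleton_length(sk, seg$pixel_size, is_skeleton = TRUE)
}

#' Per-chip sprouting metrics from one or more imaging sites
#'
#' Aggregates segmentation results of the sites of one chip into a
#' single metrics record: migration distance is averaged across sites
#' (it is an intensive, per-site readout), while area, nuclei count and
#' vessel length are extensive and summed.
#'
#' @param segs A single `segmentation_result` or a list of them (one per
#'   site); all sites must share the pixel size.
#' @param chip_id Chip identifier.
#' @param k Furthest-nuclei count for [migration_distance()].
#' @return A one-row `data.frame` with columns `chip_id`,
#'   `total_area_um2`, `distance_um`, `nuclei_count`, `length_um`,
#'   `n_sites`.
#' @export
quantify_chip <- function(segs, chip_id = "chip", k = 10) {
  if (inherits(segs, "segmentation_result")) segs <- list(segs)
  stopifnot(length(segs) >= 1,
            all(vapply(segs, inherits, TRUE, "segmentation_result")))
  ps <- vapply(segs, function(s) s$pixel_size, 0)
  if (diff(range(ps)) > 1e-9) {
    stop("pixel sizes differ across the sites of chip ", chip_id)
  }
  dist <- mean(vapply(segs, function(s) {
    migration_distance(s$nuclei, s$baseline_y, k)
  }, 0))
  data.frame(
    chip_id = chip_id,
    total_area_um2 = sum(vapply(segs, total_sprout_area, 0)),
    distance_um = dist,
    nuclei_count = sum(vapply(segs, nuclei_in_sprouts, 0L)),
    length_um = sum(vapply(segs, total_vessel_length, 0)),
    n_sites = length(segs),
    stringsAsFactors = FALSE)
}
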