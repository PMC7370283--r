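#' Detect nuclei centroids in a 2D nuclei-channel image
#'
#' Pipeline: grey-scale opening with a large disc (rolling-ball-style
#' background estimate) and subtraction, Gaussian smoothing, global Otsu
#' threshold, watershed on the smoothed intensity surface to split
#' touching nuclei (each intensity peak seeds one nucleus; peaks
#' shallower than `ws_tolerance` merge), and a size filter keeping
#' objects whose equivalent circular diameter lies in
#' `[min_diameter, max_diameter]`. Centroids are intensity-weighted
#' over each watershed region, giving sub-pixel positions, and reported
#' in um (pixel (1,1) center at (0.5, 0.5) * pixel_size).
#'
#' @param img Numeric matrix `[y, x]` of nuclei-channel intensities.
#' @param pixel_size um per pixel.
#' @param min_diameter,max_diameter Accepted nucleus diameter range, um.
#' @param smooth_sigma Gaussian smoothing sigma in um, so behaviour is
#'   independent of the acquisition resolution.
#' @param bg_radius Background-opening disc radius, um.
#' @param ws_tolerance Watershed merge tolerance, as a fraction of the
#'   normalised intensity range.
#' @return `data.frame` with columns `x`, `y` (um) and `area_um2`, one
#'   row per detected nucleus; zero rows for a blank image.
#' @export
segment_nuclei <- function(img, pixel_size, min_diameter = 7,
                           max_diameter = 25, smooth_sigma = 5,
                           bg_radius = 50, ws_tolerance = 0.02) {
  stopifnot(is.matrix(img), pixel_size > 0,
            min_diameter > 0, min_diameter < max_diameter)
  empty <- data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0))
  if (diff(range(img)) == 0) return(empty)

  x <- (img - min(img)) / diff(range(img))
  brush_px <- max(3L, 2L * as.integer(bg_radius / pixel_size / 2) + 1L)
  bg <- EBImage::opening(x, EBImage::makeBrush(brush_px, shape = "disc"))
  x <- x - bg
  sm <- EBImage::gblur(x, sigma = max(smooth_sigma / pixel_size, 0.5))
  rng <- range(sm)
  if (diff(rng) == 0) return(empty)
  thr <- EBImage::otsu(EBImage::Image(sm), range = rng)
  mask <- sm > thr
  if (!any(mask)) return(empty)

  smm <- sm
  smm[!mask] <- 0
  ws <- EBImage::watershed(EBImage::Image(smm), tolerance = ws_tolerance,
                           ext = 1)
  ws <- EBImage::imageData(ws)

  idx <- which(ws > 0)
  lab <- ws[idx]
  rc <- arrayInd(idx, dim(ws))
  wgt <- pmax(sm[idx], 0)
  area_px <- tabulate(lab)
  keep_lab <- which(
    area_px * pixel_size^2 >= pi / 4 * min_diameter^2 &
    area_px * pixel_size^2 <= pi / 4 * max_diameter^2)
  if (length(keep_lab) == 0L) return(empty)
  keep <- lab %in% keep_lab
  lab <- lab[keep]; rc <- rc[keep, , drop = FALSE]; wgt <- wgt[keep]
  wgt[wgt == 0] <- .Machine$double.eps
  wsum <- rowsum(wgt, lab)
  cy <- rowsum(wgt * (rc[, 1] - 0.5), lab) / wsum
  cx <- rowsum(wgt * (rc[, 2] - 0.5), lab) / wsum
  out <- data.frame(
    x = as.numeric(cx) * pixel_size,
    y = as.numeric(cy) * pixel_size,
    area_um2 = area_px[sort(unique(lab))] * pixel_size^2)
  out[order(out$y, out$x), , drop = FALSE]
}

#' Segment the F-actin channel into a binary vessel mask
#'
#' Gaussian smoothing, global Otsu threshold, morphological closing,
#' hole filling, and removal of connected components smaller than
#' `min_object` um^2. The foreground is everything F-actin-positive:
#' the monolayer band as well as the sprouts (downstream metrics gate on
#' the baseline).
#'
#' @param img Numeric matrix `[y, x]` of F-actin intensities.
#' @param pixel_size um per pixel.
#' @param smooth_sigma Gaussian smoothing sigma, um.
#' @param min_object Minimum object area, um^2.
#' @param close_radius Closing disc radius, um.
#' @return Logical matrix of the same dimensions as `img`.
#' @export
segment_vessel_mask <- function(img, pixel_size, smooth_sigma = 3,
                                min_object = 100, close_radius = 5) {
  stopifnot(is.matrix(img), pixel_size > 0)
  if (diff(range(img)) == 0) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  x <- (img - min(img)) / diff(range(img))
  sm <- EBImage::gblur(x, sigma = max(smooth_sigma / pixel_size, 0.5))
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  mask <- sm > thr
  if (!any(mask)) return(mask)
  brush_px <- max(3L, 2L * as.integer(close_radius / pixel_size) + 1L)
  mask <- EBImage::closing(mask, EBImage::makeBrush(brush_px, "disc"))
  mask <- EBImage::fillHull(mask) > 0
  lab <- EBImage::bwlabel(mask)
  area_px <- tabulate(lab[lab > 0])
  small <- which(area_px * pixel_size^2 < min_object)
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

# one Zhang-Suen thinning sub-iteration, vectorised over the image
.zs_subiter <- function(m, step) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  sh <- function(dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  n2 <- sh(-1, 0); n3 <- sh(-1, 1); n4 <- sh(0, 1); n5 <- sh(1, 1)
  n6 <- sh(1, 0); n7 <- sh(1, -1); n8 <- sh(0, -1); n9 <- sh(-1, -1)
  b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
  a <- (n2 == 0 & n3 == 1) + (n3 == 0 & n4 == 1) + (n4 == 0 & n5 == 1) +
       (n5 == 0 & n6 == 1) + (n6 == 0 & n7 == 1) + (n7 == 0 & n8 == 1) +
       (n8 == 0 & n9 == 1) + (n9 == 0 & n2 == 1)
  if (step == 1L) {
    cond <- n2 * n4 * n6 == 0 & n4 * n6 * n8 == 0
  } else {
    cond <- n2 * n4 * n8 == 0 & n2 * n6 * n8 == 0
  }
  del <- m == 1L & b >= 2 & b <= 6 & a == 1 & cond
  m[del] <- 0L
  list(m = m, changed = any(del))
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' Iteratively thins a binary mask to a 1-pixel-wide, 8-connected
#' skeleton. The skeleton is always a subset of the input mask, and
#' already-thin lines (including their endpoints) are preserved.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    s1 <- .zs_subiter(m, 1L)
    s2 <- .zs_subiter(s1$m, 2L)
    m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  m == 1L
}

#' Total skeleton length of a vessel mask
#'
#' Skeletonizes the mask (unless `is_skeleton = TRUE`) and sums the
#' lengths of the 8-neighbour adjacencies between skeleton pixels: 1
#' pixel per orthogonal step, sqrt(2) per diagonal step, scaled by
#' `pixel_size`. An empty mask has length 0.
#'
#' @param mask Logical matrix (vessel mask or skeleton).
#' @param pixel_size um per pixel.
#' @param is_skeleton Set `TRUE` when `mask` is already a skeleton.
#' @return Total length, um.
#' @export
skeleton_length <- function(mask, pixel_size, is_skeleton = FALSE) {
  stopifnot(pixel_size > 0)
  if (!any(mask)) return(0)
  sk <- if (is_skeleton) mask != 0 else skeletonize(mask)
  h <- nrow(sk); w <- ncol(sk)
  nh <- sum(sk[, -w] & sk[, -1])
  nv <- sum(sk[-h, ] & sk[-1, ])
  nd <- sum(sk[-h, -w] & sk[-1, -1]) + sum(sk[-h, -1] & sk[-1, -w])
  (nh + nv + sqrt(2) * nd) * pixel_size
}

#' Segment a projected chip image into vessels and nuclei
#'
#' Runs [segment_nuclei()] on the nuclei channel and
#' [segment_vessel_mask()] plus [skeletonize()] on the F-actin channel
#' of a [projected_image()], bundling the results with the baseline
#' position. The skeleton is computed for the gel region
#' (`y > baseline_y`) only — the domain of the vessel-length readout;
#' the confluent monolayer band is not a linear structure and thinning
#' it would dominate the runtime without informing any metric. Nuclei
#' outside the vessel mask are retained here; gating happens in the
#' metrics layer.
#'
#' @param proj A [projected_image()] with `nuclei` and `factin` channels.
#' @param baseline_y y-position of the monolayer/gel interface, um.
#' @param nuclei_args,vessel_args Optional lists of extra arguments for
#'   [segment_nuclei()] / [segment_vessel_mask()].
#' @return An object of class `segmentation_result`: list with
#'   `vessel_mask`, `skeleton`, `nuclei` (data.frame x/y um),
#'   `baseline_y`, `pixel_size`.
#' @export
segment_projection <- function(proj, baseline_y = 400,
                               nuclei_args = list(), vessel_args = list()) {
  stopifnot(inherits(proj, "projected_image"), baseline_y >= 0)
  for (ch in c("nuclei", "factin")) {
    if (!ch %in% names(proj$channels)) {
      stop("missing channel '", ch, "' in projected image")
    }
  }
  nuclei <- do.call(segment_nuclei, c(
    list(img = proj$channels$nuclei, pixel_size = proj$pixel_size),
    nuclei_args))
  mask <- do.call(segment_vessel_mask, c(
    list(img = proj$channels$factin, pixel_size = proj$pixel_size),
    vessel_args))
  skel <- matrix(FALSE, nrow(mask), ncol(mask))
  base_row <- floor(baseline_y / proj$pixel_size)
  if (base_row < nrow(mask)) {
    gel_rows <- (max(base_row, 0L) + 1L):nrow(mask)
    skel[gel_rows, ] <- skeletonize(mask[gel_rows, , drop = FALSE])
  }
  structure(list(
    vessel_mask = mask,
    skeleton = skel,
    nuclei = nuclei,
    baseline_y = baseline_y,
    pixel_size = proj$pixel_size), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: %d nuclei, vessel mask %d px, baseline %g um\n",
    nrow(x$nuclei), sum(x$vessel_mask), x$baseline_y))
  invisible(x)
}
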