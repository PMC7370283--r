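#' Two-channel 3D image stack for one chip site
#'
#' Container for a confocal stack of one microfluidic chip site. Arrays
#' are indexed `[y, x, z]` with pixel (1,1) at the top-left corner and y
#' increasing toward the gel (the sprouting direction); all physical
#' coordinates are derived through `pixel_size` and `z_step`.
#'
#' @param channels Named list of 3D numeric arrays with identical
#'   dimensions; conventional channel names are `nuclei` and `factin`.
#' @param pixel_size Lateral pixel size, um/pixel (> 0).
#' @param z_step Axial step between planes, um.
#' @param bit_depth Bits per sample (intensities must lie in
#'   `[0, 2^bit_depth - 1]`).
#' @return An object of class `chip_stack`.
#' @export
chip_stack <- function(channels, pixel_size, z_step = 1, bit_depth = 16) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), pixel_size > 0, z_step > 0)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("every channel must be a 3D array [y, x, z]")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all channels must have identical dimensions")
  }
  vmax <- 2^bit_depth - 1
  rng <- range(vapply(channels, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > vmax) {
    stop(sprintf("intensities outside [0, %d] for bit depth %d",
                 vmax, bit_depth))
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step, bit_depth = as.integer(bit_depth)),
            class = "chip_stack")
}

#' @export
print.chip_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "chip_stack: %d channel(s) [%s], %d x %d px x %d z, %.3g um/px, %.3g um z-step\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3], x$pixel_size, x$z_step))
  invisible(x)
}

#' 2D projected image (one or more channels)
#'
#' @param channels Named list of 2D numeric matrices of equal dimensions.
#' @param pixel_size Lateral pixel size, um/pixel.
#' @param origin `(x, y)` offset in um of pixel (1,1), used after
#'   stitching.
#' @return An object of class `projected_image`.
#' @export
projected_image <- function(channels, pixel_size, origin = c(0, 0)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), pixel_size > 0, length(origin) == 2)
  dims <- vapply(channels, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L) {
    stop("all channels must have identical dimensions")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "projected_image")
}

.metadata_path <- function(path) paste0(path, ".json")

#' Write a chip stack to disk
#'
#' Saves the stack as a multi-page 16-bit TIFF (pages ordered z-major
#' with channels interleaved) together with a JSON metadata sidecar
#' (`<path>.json`) recording pixel size, z-step, bit depth and channel
#' names, so that [read_stack()] can reconstruct the object without
#' external configuration.
#'
#' @param stack A [chip_stack()] (a [projected_image()] is accepted and
#'   written as a single-plane stack).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "projected_image")) {
    stack <- chip_stack(lapply(stack$channels, function(m) {
      array(m, dim = c(dim(m), 1L))
    }), pixel_size = stack$pixel_size, z_step = 1)
  }
  stopifnot(inherits(stack, "chip_stack"))
  vmax <- 2^stack$bit_depth - 1
  nz <- dim(stack$channels[[1]])[3]
  pages <- vector("list", nz * length(stack$channels))
  i <- 1L
  for (z in seq_len(nz)) {
    for (ch in stack$channels) {
      pages[[i]] <- ch[, , z] / vmax
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size, z_step_um = stack$z_step,
         bit_depth = stack$bit_depth, n_z = nz,
         channels = names(stack$channels), page_order = "z_major"),
    .metadata_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# pull PhysicalSizeX / PhysicalSizeZ out of an OME-XML description string
.parse_ome_sizes <- function(desc) {
  grab <- function(attr) {
    m <- regmatches(desc, regexpr(sprintf('%s="[0-9.eE+-]+"', attr), desc))
    if (length(m)) as.numeric(gsub('.*"([0-9.eE+-]+)"', "\\1", m)) else NULL
  }
  list(pixel_size = grab("PhysicalSizeX"), z_step = grab("PhysicalSizeZ"))
}

#' Read a chip stack from a TIFF file
#'
#' Pages are interpreted z-major with `length(channels)` interleaved
#' channels. Geometry metadata is resolved in order of preference from
#' (1) an OME-XML image description embedded in the file, (2) the JSON
#' sidecar written by [write_stack()], (3) the `pixel_size` / `z_step`
#' arguments; an error is raised if none supplies the pixel size.
#'
#' @param path TIFF file path.
#' @param channels Character vector of channel names; defaults to the
#'   sidecar value or `c("nuclei", "factin")` when the page count is
#'   even, `"nuclei"` otherwise.
#' @param pixel_size,z_step Fallback geometry (um) when no metadata is
#'   found.
#' @return A [chip_stack()].
#' @export
read_stack <- function(path, channels = NULL, pixel_size = NULL,
                       z_step = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("not a readable TIFF file: ", path,
                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF contains no images: ", path)

  meta <- list()
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && grepl("PhysicalSize", desc)) {
    ome <- .parse_ome_sizes(desc)
    meta$pixel_size_um <- ome$pixel_size
    meta$z_step_um <- ome$z_step
  }
  side <- .metadata_path(path)
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (f in names(sc)) if (is.null(meta[[f]])) meta[[f]] <- sc[[f]]
  }
  if (is.null(channels)) {
    channels <- meta$channels %||%
      (if (length(pages) %% 2 == 0) c("nuclei", "factin") else "nuclei")
  }
  ps <- meta$pixel_size_um %||% pixel_size
  zs <- meta$z_step_um %||% z_step %||% 1
  if (is.null(ps)) {
    stop("pixel size not present in metadata; pass pixel_size explicitly")
  }
  nc <- length(channels)
  if (length(pages) %% nc != 0L) {
    stop(sprintf("page count %d is not a multiple of %d channels (%s)",
                 length(pages), nc, paste(channels, collapse = ", ")))
  }
  nz <- length(pages) %/% nc
  d <- dim(pages[[1]])
  arrs <- lapply(seq_len(nc), function(ci) {
    a <- array(0, dim = c(d[1], d[2], nz))
    for (z in seq_len(nz)) a[, , z] <- pages[[(z - 1L) * nc + ci]]
    a
  })
  names(arrs) <- channels
  chip_stack(arrs, pixel_size = ps, z_step = zs,
             bit_depth = attr(pages[[1]], "bits.per.sample") %||% 16)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-intensity projection of a chip stack
#'
#' Collapses each channel to 2D by taking the per-pixel maximum over z.
#' Applied to a single-plane stack this is the identity on the plane.
#'
#' @param stack A [chip_stack()].
#' @return A [projected_image()] with the same channels and pixel size.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "chip_stack"))
  proj <- lapply(stack$channels, function(a) {
    nz <- dim(a)[3]
    m <- a[, , 1]
    if (nz > 1) for (z in 2:nz) m <- pmax(m, a[, , z])
    m
  })
  projected_image(proj, pixel_size = stack$pixel_size)
}

# 2D cross-power-spectrum (phase) correlation; returns the real
# correlation surface, peak index = translation mod array size
.phase_correlation <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  Re(stats::fft(cross / mag, inverse = TRUE)) / length(a)
}

#' Stitch the two vertically overlapping sites of one chip
#'
#' Site B is assumed to continue site A in +y with a nominal fractional
#' overlap (10% for the standard two-site acquisition). The translation
#' is refined by phase correlation of the two projections; if the
#' correlation peak lies more than 10% of the frame away from the
#' nominal offset the nominal offset is used instead, with a warning.
#' The overlap band is fused by linear distance-weighted blending: the
#' blend weight ramps from 1 (pure A) at the A-side edge of the overlap
#' to 0 at the B-side edge, and the two weights sum to 1 everywhere.
#'
#' @param img_a,img_b [projected_image()]s with equal pixel sizes and
#'   matching channel sets.
#' @param nominal_overlap Fractional overlap in `(0, 0.5]`; default 0.1.
#' @return A fused [projected_image()] of height about
#'   `hA + hB - overlap`.
#' @export
stitch_pair <- function(img_a, img_b, nominal_overlap = 0.1) {
  stopifnot(inherits(img_a, "projected_image"),
            inherits(img_b, "projected_image"))
  if (abs(img_a$pixel_size - img_b$pixel_size) > 1e-9) {
    stop("pixel sizes differ between the two sites")
  }
  if (nominal_overlap <= 0 || nominal_overlap > 0.5) {
    stop("nominal_overlap must be in (0, 0.5]")
  }
  if (!setequal(names(img_a$channels), names(img_b$channels))) {
    stop("channel sets differ between the two sites")
  }
  ha <- nrow(img_a$channels[[1]]); wa <- ncol(img_a$channels[[1]])
  hb <- nrow(img_b$channels[[1]]); wb <- ncol(img_b$channels[[1]])
  nom_dy <- round(ha * (1 - nominal_overlap))
  nom_dx <- 0L

  # registration on the channel-summed images, zero-padded to a common
  # canvas so the correlation peak index equals the translation
  ny <- ha + hb; nx <- wa + wb
  pa <- matrix(0, ny, nx); pb <- matrix(0, ny, nx)
  suma <- Reduce(`+`, img_a$channels); sumb <- Reduce(`+`, img_b$channels)
  pa[seq_len(ha), seq_len(wa)] <- suma - mean(suma)
  pb[seq_len(hb), seq_len(wb)] <- sumb - mean(sumb)

  use_nominal <- FALSE
  if (stats::sd(suma) == 0 || stats::sd(sumb) == 0) {
    use_nominal <- TRUE  # featureless images carry no registration signal
  } else {
    cc <- .phase_correlation(pa, pb)
    peak <- arrayInd(which.max(cc), dim(cc))
    dy <- peak[1] - 1L; dx <- peak[2] - 1L
    if (dy > ny / 2) dy <- dy - ny
    if (dx > nx / 2) dx <- dx - nx
    if (abs(dy - nom_dy) > 0.1 * ha || abs(dx - nom_dx) > 0.1 * wa) {
      warning(sprintf(
        "correlation peak (dy=%d, dx=%d) is >10%% of the frame from the nominal offset (dy=%d); falling back to nominal",
        dy, dx, nom_dy))
      use_nominal <- TRUE
    }
  }
  if (use_nominal) { dy <- nom_dy; dx <- nom_dx }

  # canvas placement: A at (0, oxa), B at (dy, oxb)
  oxa <- max(0L, -dx); oxb <- max(0L, dx)
  cw <- max(wa + oxa, wb + oxb)
  chh <- max(ha, dy + hb)

  ovl_lo <- dy + 1L; ovl_hi <- ha  # canvas rows where both sites exist
  n_ovl <- ovl_hi - ovl_lo + 1L
  fused <- lapply(names(img_a$channels), function(nm) {
    ca <- matrix(NA_real_, chh, cw); cb <- matrix(NA_real_, chh, cw)
    ca[seq_len(ha), oxa + seq_len(wa)] <- img_a$channels[[nm]]
    cb[dy + seq_len(hb), oxb + seq_len(wb)] <- img_b$channels[[nm]]
    wA <- matrix(1, chh, cw)
    if (n_ovl >= 1) {
      alpha <- if (n_ovl == 1) 0.5 else
        (seq.int(ovl_lo, ovl_hi) - ovl_lo) / (ovl_hi - ovl_lo)
      wA[ovl_lo:ovl_hi, ] <- 1 - alpha
    }
    out <- ifelse(is.na(ca), cb,
                  ifelse(is.na(cb), ca, wA * ca + (1 - wA) * cb))
    out[is.na(out)] <- 0
    out
  })
  names(fused) <- names(img_a$channels)
  projected_image(fused, pixel_size = img_a$pixel_size,
                  origin = c(-oxa * img_a$pixel_size, 0))
}
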