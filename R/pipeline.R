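#' Run configuration for the quantification pipeline
#'
#' Validates and freezes everything a pipeline run depends on. Exactly
#' one of `input_paths` (measured data) and `synthetic` (simulated data)
#' must be supplied.
#'
#' @param layout A [plate_layout()] or path to a layout CSV with columns
#'   `chip_id`, `compound`, `concentration`, `role`.
#' @param synthetic `NULL`, or a list with optional elements `params`
#'   (arguments for [sprouting_model_params()]) and `geometry`
#'   (arguments for [chip_geometry()]).
#' @param input_paths `NULL`, or a named list/vector mapping `chip_id`
#'   to TIFF path(s); a chip may map to several per-site paths.
#' @param baseline_y Baseline position, um.
#' @param k Furthest-nuclei count for the distance readout.
#' @param pixel_size Fallback pixel size (um) for stacks without
#'   metadata.
#' @param nuclei_args,vessel_args Extra segmentation arguments (see
#'   [segment_projection()]).
#' @param seed Integer master seed for the run.
#' @param out_dir Optional output directory; created when missing.
#' @return An object of class `run_config` carrying a `hash` field (MD5
#'   of the canonical JSON serialisation, stamped into every output).
#' @export
run_config <- function(layout, synthetic = NULL, input_paths = NULL,
                       baseline_y = 400, k = 10, pixel_size = 0.677,
                       nuclei_args = list(), vessel_args = list(),
                       seed = 1, out_dir = NULL) {
  if (is.null(synthetic) == is.null(input_paths)) {
    stop("exactly one of 'synthetic' and 'input_paths' must be set")
  }
  if (is.character(layout)) layout <- read_plate_layout(layout)
  stopifnot(inherits(layout, "plate_layout"), baseline_y >= 0, k >= 1,
            pixel_size > 0)
  if (!is.null(synthetic)) {
    synthetic$params <- do.call(sprouting_model_params,
                                as.list(synthetic$params))
    synthetic$geometry <- do.call(chip_geometry,
                                  as.list(synthetic$geometry))
  }
  cfg <- structure(
    list(layout = layout, synthetic = synthetic, input_paths = input_paths,
         baseline_y = baseline_y, k = k, pixel_size = pixel_size,
         nuclei_args = nuclei_args, vessel_args = vessel_args,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' MD5 hash of a run configuration
#'
#' Stable fingerprint of the configuration (output directory excluded),
#' stamped into every table the pipeline writes so outputs of different
#' runs cannot be mixed silently.
#'
#' @param config A [run_config()].
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL; x$hash <- NULL
  x$layout <- as.data.frame(x$layout)
  if (!is.null(x$synthetic)) {
    x$synthetic$params <- unclass(x$synthetic$params)
    x$synthetic$geometry <- unclass(x$synthetic$geometry)
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tf))
}

#' Read a plate layout CSV
#'
#' @param path CSV with columns `chip_id`, `compound`, `concentration`,
#'   `role`.
#' @return A [plate_layout()].
#' @export
read_plate_layout <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chip_id", "compound", "concentration", "role")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("layout CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  plate_layout(d$chip_id, d$compound, d$concentration, d$role)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("angioscreen"))
}

# deterministic per-chip seed derived from the master seed
.chip_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 100003 + i * 7919) %% 2147483647)
}

.na_metrics_row <- function(chip_id) {
  n <- length(chip_id)
  data.frame(chip_id = chip_id, total_area_um2 = rep(NA_real_, n),
             distance_um = rep(NA_real_, n),
             nuclei_count = rep(NA_integer_, n),
             length_um = rep(NA_real_, n), n_sites = rep(NA_integer_, n),
             stringsAsFactors = FALSE)
}

# image -> segmentation -> metrics for one chip (one or more sites)
.quantify_sites <- function(projs, config, chip_id) {
  segs <- lapply(projs, segment_projection,
                 baseline_y = config$baseline_y,
                 nuclei_args = config$nuclei_args,
                 vessel_args = config$vessel_args)
  quantify_chip(segs, chip_id = chip_id, k = config$k)
}

#' Quantify every chip of a plate
#'
#' For a synthetic run, each chip in the layout is rendered at its
#' layout concentration (with a per-chip seed derived from the master
#' seed), max-projected, segmented and quantified. For a measured run,
#' the chip's stack(s) are read from `input_paths`; a chip whose file
#' cannot be read produces a row of NAs and a warning rather than
#' aborting the plate. Results carry the configuration hash and package
#' version; when `config$out_dir` is set they are also written to
#' `metrics.csv`.
#'
#' @param config A [run_config()].
#' @return Per-chip metric `data.frame` with layout columns, the
#'   [quantify_chip()] readouts, `config_hash` and `version`.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  layout <- config$layout
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    cid <- layout$chip_id[i]
    rows[[i]] <- tryCatch({
      if (!is.null(config$synthetic)) {
        r <- render_chip_stack(config$synthetic$params,
                               config$synthetic$geometry,
                               concentration = layout$concentration[i],
                               seed = .chip_seed(config$seed, i))
        projs <- list(max_project(r$stack))
      } else {
        paths <- config$input_paths[[cid]]
        if (is.null(paths)) stop("no input path for chip ", cid)
        projs <- lapply(paths, function(p) {
          max_project(read_stack(p, pixel_size = config$pixel_size))
        })
      }
      .quantify_sites(projs, config, cid)
    }, error = function(e) {
      warning("chip ", cid, " failed: ", conditionMessage(e), call. = FALSE)
      .na_metrics_row(cid)
    })
  }
  met <- if (length(rows)) do.call(rbind, rows) else .na_metrics_row(character(0))
  out <- cbind(
    layout[, c("chip_id", "compound", "concentration", "role")],
    met[, setdiff(names(met), "chip_id"), drop = FALSE])
  names(out)[names(out) == "concentration"] <- "concentration_nM"
  out$config_hash <- rep(config$hash, nrow(out))
  out$version <- rep(.pkg_version(), nrow(out))
  rownames(out) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  out
}

#' Plate-level QC report
#'
#' Computes the assay-performance statistics (signal window, Z-factor,
#' assay variability ratio, CVs) and the acceptance flags for each
#' readout, from the max- and min-control groups of a per-chip metric
#' table.
#'
#' @param metrics Metric `data.frame` (from [run_quantify()] or
#'   [simulate_metric_table()]) or path to a metrics CSV.
#' @param readouts Metric columns to report on.
#' @param out_dir Optional directory; when set, writes `qc_report.json`
#'   and a human-readable `qc_report.txt`.
#' @return A list with one element per readout, each holding `gmax`,
#'   `gmin`, `performance` and `flags`, plus attribute `config_hash`
#'   when present in the input.
#' @export
run_qc <- function(metrics, readouts = c("total_area_um2", "distance_um",
                                         "nuclei_count"),
                   out_dir = NULL) {
  if (is.character(metrics)) {
    metrics <- utils::read.csv(metrics, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metrics))
  if (!"role" %in% names(metrics)) stop("metrics table has no 'role' column")
  for (role in c("max_control", "min_control")) {
    n <- sum(metrics$role == role)
    if (n < 2) {
      stop("control role '", role, "' has ", n,
           " chip(s); at least 2 are required")
    }
  }
  report <- lapply(readouts, function(rd) {
    if (!rd %in% names(metrics)) stop("no metric column '", rd, "'")
    vmax <- metrics[[rd]][metrics$role == "max_control"]
    vmin <- metrics[[rd]][metrics$role == "min_control"]
    gmax <- group_stats(vmax[is.finite(vmax)])
    gmin <- group_stats(vmin[is.finite(vmin)])
    perf <- assay_performance(gmax, gmin)
    list(gmax = gmax, gmin = gmin, performance = perf,
         flags = evaluate_acceptance(perf))
  })
  names(report) <- readouts
  attr(report, "config_hash") <- metrics$config_hash[1] %||% NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ser <- lapply(report, function(r) {
      c(unclass(r$performance),
        list(flags = r$flags,
             gmax = unclass(r$gmax), gmin = unclass(r$gmin)))
    })
    jsonlite::write_json(
      list(config_hash = attr(report, "config_hash"),
           version = .pkg_version(), readouts = ser),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    txt <- vapply(names(report), function(rd) {
      p <- report[[rd]]$performance; f <- report[[rd]]$flags
      sprintf(paste0(
        "%-15s SW %6.2f  Z' %5.3f  AVR %5.3f  CVmax %5.1f%%  CVmin %5.1f%%",
        "  [%s]"),
        rd, p$sw, p$z_factor, p$avr, p$cv_max, p$cv_min,
        if (f$pass) "PASS" else "FAIL")
    }, "")
    writeLines(c("Plate QC report", txt),
               file.path(out_dir, "qc_report.txt"))
  }
  report
}

#' Dose-response fits per compound
#'
#' For every compound in the metric table (other than `"none"`), pools
#' that compound's rows with the plate's untreated max-control rows
#' (concentration 0), fits a 4PL inhibition curve to the chosen readout
#' and attaches a bootstrap IC50 confidence interval. A failing
#' compound yields a non-converged row; the run continues.
#'
#' @param metrics Metric `data.frame` or CSV path.
#' @param readout Metric column to fit (default `"distance_um"`).
#' @param n_boot Bootstrap resamples for the CI (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param out_dir Optional directory; when set, writes
#'   `dose_response.json`.
#' @return `data.frame` with one row per compound: `compound`, `ic50`,
#'   `ci_low`, `ci_high`, `hill`, `top`, `bottom`, `converged`,
#'   `n_points`. The fit objects are attached as attribute `fits`.
#' @export
run_dose_response <- function(metrics, readout = "distance_um",
                              n_boot = 200, seed = 1, out_dir = NULL) {
  if (is.character(metrics)) {
    metrics <- utils::read.csv(metrics, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metrics), readout %in% names(metrics))
  compounds <- setdiff(unique(metrics$compound), "none")
  if (length(compounds) == 0L) stop("no treated compounds in the table")
  ctrl <- metrics[metrics$role == "max_control", , drop = FALSE]
  fits <- list()
  rows <- lapply(compounds, function(cmp) {
    sub <- rbind(ctrl, metrics[metrics$compound == cmp, , drop = FALSE])
    fit <- tryCatch({
      f <- fit_4pl(sub$concentration_nM, sub[[readout]])
      if (f$converged && n_boot > 0) {
        f <- ic50_confidence_interval(f, n_boot = n_boot, seed = seed)
      }
      f
    }, error = function(e) {
      warning("dose-response fit for ", cmp, " failed: ",
              conditionMessage(e), call. = FALSE)
      structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                     hill = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     n_points = nrow(sub), converged = FALSE,
                     message = conditionMessage(e)),
                class = "dose_response_fit")
    })
    fits[[cmp]] <<- fit
    data.frame(compound = cmp, ic50 = fit$ic50, ci_low = fit$ci_low,
               ci_high = fit$ci_high, hill = fit$hill, top = fit$top,
               bottom = fit$bottom, converged = fit$converged,
               n_points = fit$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(version = .pkg_version(), readout = readout, fits = out),
      file.path(out_dir, "dose_response.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}

#' Build a reusable synthetic benchmark fixture set
#'
#' Renders every chip of the configured synthetic plate to disk
#' (TIFF + metadata sidecar) and writes a `manifest.json` recording the
#' configuration hash, per-chip ground truth and the MD5 checksum of
#' each image, so a regenerated or copied benchmark can be verified
#' bit-for-bit with [verify_benchmark()].
#'
#' @param config A [run_config()] with a synthetic source and `out_dir`
#'   set.
#' @return Path of the manifest file, invisibly.
#' @export
run_synthetic_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$synthetic),
            !is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- config$layout
  chips <- lapply(seq_len(nrow(layout)), function(i) {
    r <- render_chip_stack(config$synthetic$params,
                           config$synthetic$geometry,
                           concentration = layout$concentration[i],
                           seed = .chip_seed(config$seed, i))
    fn <- file.path(config$out_dir, paste0(layout$chip_id[i], ".tif"))
    write_stack(r$stack, fn)
    list(chip_id = layout$chip_id[i], file = basename(fn),
         md5 = unname(tools::md5sum(fn)),
         concentration = layout$concentration[i],
         true_distance_um = r$truth$true_distance,
         true_area_um2 = r$truth$true_area,
         true_nuclei_in_sprouts = r$truth$true_nuclei_in_sprouts)
  })
  manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(config_hash = config$hash, seed = config$seed,
         version = .pkg_version(), chips = chips),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify a synthetic benchmark directory against its manifest
#'
#' @param dir Directory containing `manifest.json` and the chip TIFFs.
#' @return Logical vector, one element per chip (TRUE when the file
#'   exists and its MD5 matches), named by chip id.
#' @export
verify_benchmark <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  chips <- manifest$chips
  ok <- vapply(seq_len(nrow(chips)), function(i) {
    f <- file.path(dir, chips$file[i])
    file.exists(f) && identical(unname(tools::md5sum(f)), chips$md5[i])
  }, TRUE)
  names(ok) <- chips$chip_id
  ok
}
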