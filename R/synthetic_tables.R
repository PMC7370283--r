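#' Parameters of the synthetic sprouting model
#'
#' Collects the parameters that define the dose-dependent sprouting
#' behaviour of a synthetic microvessel chip. The inhibitor response
#' follows a four-parameter logistic (4PL) inhibition model (see
#' [expected_response()]); between-chip variability is multiplicative
#' Gaussian noise truncated at zero.
#'
#' Defaults describe an untreated control chip sprouting 250 um into the
#' gel with 13% between-chip CV (the variability level of a well-behaved
#' distance readout), ten sprouts per chip and nuclei spaced every 20 um
#' along a sprout, with the monolayer/gel interface at y = 400 um.
#'
#' @param D0 Control (uninhibited) migration distance, um.
#' @param Imax Maximal fractional inhibition, in \[0, 1\]; 1 means
#'   sprouting is fully suppressed at saturating dose.
#' @param IC50 Half-maximal inhibitory concentration (same units as the
#'   concentrations passed to [expected_response()], typically nM).
#' @param hill Hill slope, > 0.
#' @param cv_chip Between-chip coefficient of variation of the distance
#'   readout (fraction, >= 0).
#' @param sprouts_per_chip Number of sprouts rendered/assumed per chip.
#' @param nuclei_spacing Spacing of nuclei along a sprout, um.
#' @param baseline_y y-position (um) of the monolayer/gel interface;
#'   sprouting metrics are measured beyond it.
#' @param sprout_width Width of a rendered sprout, um.
#' @param seed Optional integer seed giving deterministic simulation when
#'   a function is not passed an explicit seed.
#' @return An object of class `sprouting_model_params`.
#' @export
sprouting_model_params <- function(D0 = 250, Imax = 1, IC50 = 20, hill = 1,
                                   cv_chip = 0.13, sprouts_per_chip = 10,
                                   nuclei_spacing = 20, baseline_y = 400,
                                   sprout_width = 20, seed = NULL) {
  stopifnot(D0 > 0, Imax >= 0, Imax <= 1, IC50 > 0, hill > 0,
            cv_chip >= 0, sprouts_per_chip >= 0, nuclei_spacing > 0,
            baseline_y >= 0, sprout_width > 0)
  structure(
    list(D0 = D0, Imax = Imax, IC50 = IC50, hill = hill, cv_chip = cv_chip,
         sprouts_per_chip = as.integer(sprouts_per_chip),
         nuclei_spacing = nuclei_spacing, baseline_y = baseline_y,
         sprout_width = sprout_width, seed = seed),
    class = "sprouting_model_params"
  )
}

#' Expected migration distance under an inhibitor concentration
#'
#' Evaluates the 4PL inhibition model
#' \deqn{E(c) = D_0 \left(1 - I_{max}\frac{c^h}{c^h + IC_{50}^h}\right)}
#' which decreases monotonically from `D0` at `c = 0` towards
#' `D0 * (1 - Imax)` at saturating dose, passing through the half-maximal
#' inhibition point at `c = IC50` (when `Imax = 1` that is `D0 / 2`).
#'
#' @param conc Concentration(s), >= 0, in the units of `params$IC50`.
#' @param params A [sprouting_model_params()] object.
#' @return Expected migration distance(s), um; vectorised over `conc`.
#' @export
expected_response <- function(conc, params) {
  stopifnot(inherits(params, "sprouting_model_params"))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and non-negative")
  }
  frac <- ifelse(conc == 0, 0,
                 conc^params$hill / (conc^params$hill + params$IC50^params$hill))
  params$D0 * (1 - params$Imax * frac)
}

#' Plate layout mapping chips to compounds and roles
#'
#' @param chip_id Character vector of unique chip identifiers.
#' @param compound Compound name per chip (`"none"` for untreated).
#' @param concentration Concentration per chip, >= 0.
#' @param role One of `"max_control"`, `"min_control"`, `"test"` per chip.
#' @return A `data.frame` of class `plate_layout`.
#' @export
plate_layout <- function(chip_id, compound, concentration, role) {
  n <- length(chip_id)
  if (length(compound) == 1L) compound <- rep(compound, n)
  if (length(concentration) == 1L) concentration <- rep(concentration, n)
  if (length(role) == 1L) role <- rep(role, n)
  stopifnot(length(compound) == n, length(concentration) == n,
            length(role) == n)
  if (anyDuplicated(chip_id)) stop("chip_id values must be unique")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  bad <- setdiff(unique(role), c("max_control", "min_control", "test"))
  if (length(bad)) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (expected max_control / min_control / test)")
  }
  structure(
    data.frame(chip_id = as.character(chip_id), compound = compound,
               concentration = concentration, role = role,
               stringsAsFactors = FALSE),
    class = c("plate_layout", "data.frame")
  )
}

#' Control-plate layout with max- and min-signal groups
#'
#' Convenience constructor for an assay-characterisation plate: `n_max`
#' untreated chips (0 nM, maximum signal) and `n_min` chips at a fully
#' inhibiting dose (minimum signal). Defaults mirror a 15/14 control
#' design with 50 nM of inhibitor as the min-signal condition.
#'
#' @param n_max,n_min Group sizes.
#' @param compound Inhibitor name for the min-signal group.
#' @param min_conc Fully inhibiting concentration for the min-signal group.
#' @return A [plate_layout()].
#' @export
control_plate_layout <- function(n_max = 15, n_min = 14,
                                 compound = "sunitinib", min_conc = 50) {
  plate_layout(
    chip_id = sprintf("chip%02d", seq_len(n_max + n_min)),
    compound = c(rep("none", n_max), rep(compound, n_min)),
    concentration = c(rep(0, n_max), rep(min_conc, n_min)),
    role = c(rep("max_control", n_max), rep("min_control", n_min))
  )
}

# multiplicative Gaussian noise truncated at zero (rejection sampling);
# negligible truncation mass for the CVs used here, but distances must be
# non-negative by construction
.rtrunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0]
  }
  x
}

# expected values of the derived per-chip readouts given an expected
# migration distance
.expected_metrics <- function(e_dist, params) {
  list(
    distance = e_dist,
    area = e_dist * params$sprout_width * params$sprouts_per_chip,
    nuclei = e_dist / params$nuclei_spacing * params$sprouts_per_chip,
    length = e_dist * params$sprouts_per_chip
  )
}

#' Simulate a table of per-chip sprouting metrics for a plate
#'
#' Draws per-chip readouts for every chip in `layout`. The migration
#' distance of a chip at concentration c is drawn from a Normal with mean
#' `expected_response(c, params)` and SD `cv_chip` times that mean,
#' truncated at zero; total area, nuclei count and total vessel length
#' are derived readouts (proportional to distance through the sprout
#' count, width and nucleus spacing) carrying the same relative noise.
#'
#' @param layout A [plate_layout()].
#' @param params A [sprouting_model_params()].
#' @param replicates Number of simulated measurements per layout row
#'   (>= 1); replicate rows get suffixed chip ids.
#' @param seed Optional integer seed (defaults to `params$seed`).
#' @return A `data.frame` with one row per chip x replicate and columns
#'   `chip_id`, `compound`, `concentration_nM`, `role`, `total_area_um2`,
#'   `distance_um`, `nuclei_count`, `length_um`, `n_sites`.
#' @export
simulate_metric_table <- function(layout, params, replicates = 1,
                                  seed = params$seed) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(params, "sprouting_model_params"), replicates >= 1)
  if (nrow(layout) == 0L) stop("empty plate layout")
  if (!is.null(seed)) set.seed(seed)

  idx <- rep(seq_len(nrow(layout)), each = replicates)
  rep_no <- rep(seq_len(replicates), times = nrow(layout))
  chip_id <- layout$chip_id[idx]
  if (replicates > 1) chip_id <- sprintf("%s_r%d", chip_id, rep_no)

  e_dist <- expected_response(layout$concentration[idx], params)
  ex <- .expected_metrics(e_dist, params)
  n <- length(idx)
  dist <- .rtrunc0(n, ex$distance, params$cv_chip * ex$distance)
  area <- .rtrunc0(n, ex$area, params$cv_chip * ex$area)
  nuc <- round(.rtrunc0(n, ex$nuclei, params$cv_chip * ex$nuclei))
  len <- .rtrunc0(n, ex$length, params$cv_chip * ex$length)

  data.frame(
    chip_id = chip_id,
    compound = layout$compound[idx],
    concentration_nM = layout$concentration[idx],
    role = layout$role[idx],
    total_area_um2 = area,
    distance_um = dist,
    nuclei_count = as.integer(nuc),
    length_um = len,
    n_sites = 1L,
    stringsAsFactors = FALSE
  )
}

#' Simulate a dose-response metric table
#'
#' Builds a layout with `n_per_conc` chips at each concentration (0 nM
#' rows are labelled `max_control`, all others `test`) and simulates it
#' with [simulate_metric_table()]. At least four distinct concentrations
#' are required for the 4PL fit downstream to be identifiable.
#'
#' @param concentrations Numeric vector of >= 4 distinct doses (may
#'   include 0 for vehicle control).
#' @param params A [sprouting_model_params()].
#' @param n_per_conc Chips per concentration.
#' @param seed Optional integer seed.
#' @param compound Compound label for the table.
#' @return A per-chip metric table as in [simulate_metric_table()].
#' @export
generate_dose_response_dataset <- function(concentrations, params,
                                           n_per_conc = 8,
                                           seed = params$seed,
                                           compound = "sunitinib") {
  concentrations <- sort(unique(concentrations))
  if (length(concentrations) < 4L) {
    stop("at least 4 distinct concentrations are needed for a 4PL fit")
  }
  stopifnot(n_per_conc >= 1)
  conc <- rep(concentrations, each = n_per_conc)
  layout <- plate_layout(
    chip_id = sprintf("c%g_%02d", conc, rep(seq_len(n_per_conc),
                                            times = length(concentrations))),
    compound = ifelse(conc == 0, "none", compound),
    concentration = conc,
    role = ifelse(conc == 0, "max_control", "test")
  )
  simulate_metric_table(layout, params, replicates = 1, seed = seed)
}
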