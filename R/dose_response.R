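# 4PL inhibition curve on the log10-dose axis; logc = -Inf encodes the
# vehicle control (c = 0), whose inhibition fraction is exactly 0
.pred_4pl <- function(logc, top, bottom, logic50, hill) {
  frac <- ifelse(is.infinite(logc), 0, 10^(hill * (logc - logic50)))
  bottom + (top - bottom) / (1 + frac)
}

#' Fit a four-parameter logistic inhibition curve
#'
#' Fits \deqn{R(c) = bottom + \frac{top - bottom}{1 + (c / IC_{50})^h}}
#' to per-chip responses by nonlinear least squares
#' (Levenberg-Marquardt) on the log10-concentration axis. The vehicle
#' control (c = 0) is handled exactly: its inhibition fraction is 0, so
#' it anchors `top` without any pseudo-dose placement.
#' `bottom` is constrained to be non-negative; `top`
#' starts at the mean response of the lowest dose and IC50 at the
#' geometric mean of the nonzero doses. Non-convergence (including
#' constant responses, for which the curve is not identifiable) is
#' reported through `converged = FALSE` and a diagnostic message, never
#' an exception. A fit whose span (`top - bottom`) does not exceed twice
#' the residual SD is likewise flagged as non-converged: the data show
#' no resolvable dose dependence.
#'
#' @param concentrations Numeric vector of doses (>= 0); at least 4
#'   distinct values.
#' @param responses Numeric vector of responses, same length.
#' @return An object of class `dose_response_fit`: list with `top`,
#'   `bottom`, `ic50`, `hill`, `ci_low`, `ci_high` (NA until
#'   [ic50_confidence_interval()] is run), `n_points`, `converged`,
#'   `message`, `residuals` and the fitting `data`.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  ok <- is.finite(concentrations) & is.finite(responses)
  concentrations <- concentrations[ok]; responses <- responses[ok]
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (length(unique(concentrations)) < 4L) {
    stop("at least 4 distinct concentrations are required")
  }
  dat <- data.frame(conc = concentrations, resp = responses)
  fail <- function(msg) {
    structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                   hill = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   n_points = nrow(dat), converged = FALSE, message = msg,
                   residuals = rep(NA_real_, nrow(dat)), data = dat),
              class = "dose_response_fit")
  }
  if (stats::sd(responses) == 0) {
    return(fail("constant responses: 4PL parameters are not identifiable"))
  }
  nz <- dat$conc[dat$conc > 0]
  if (length(nz) == 0L) stop("all concentrations are zero")
  logc <- ifelse(dat$conc == 0, -Inf, log10(dat$conc))
  start <- list(
    top = mean(dat$resp[dat$conc == min(dat$conc)]),
    bottom = max(min(tapply(dat$resp, dat$conc, mean)), 0),
    logic50 = mean(log10(nz)),
    hill = 1)
  lower <- c(top = -Inf, bottom = 0, logic50 = log10(min(nz)) - 3,
             hill = 0.05)
  upper <- c(top = Inf, bottom = Inf, logic50 = log10(max(nz)) + 3,
             hill = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ .pred_4pl(logc, top, bottom, logic50, hill),
      data = data.frame(resp = dat$resp, logc = logc),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) conditionMessage(e))
  if (is.character(fit)) return(fail(fit))
  cf <- stats::coef(fit)
  res <- as.numeric(stats::residuals(fit))
  span <- cf["top"] - cf["bottom"]
  if (is.finite(span) && span <= 2 * stats::sd(res)) {
    out <- fail(sprintf(
      "no significant dose dependence: fitted span %.3g <= 2 x residual SD %.3g",
      span, stats::sd(res)))
    out$top <- unname(cf["top"]); out$bottom <- unname(cf["bottom"])
    out$ic50 <- unname(10^cf["logic50"]); out$hill <- unname(cf["hill"])
    out$residuals <- res
    return(out)
  }
  structure(list(
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    ic50 = unname(10^cf["logic50"]), hill = unname(cf["hill"]),
    ci_low = NA_real_, ci_high = NA_real_,
    n_points = nrow(dat), converged = TRUE, message = "converged",
    residuals = as.numeric(stats::residuals(fit)), data = dat),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("dose_response_fit: NOT converged (", x$message, ")\n", sep = "")
  } else {
    ci <- if (is.na(x$ci_low)) "" else
      sprintf(" (95%% CI %.3g-%.3g)", x$ci_low, x$ci_high)
    cat(sprintf(
      "dose_response_fit: IC50 %.4g%s, hill %.3g, top %.4g, bottom %.4g, n %d\n",
      x$ic50, ci, x$hill, x$top, x$bottom, x$n_points))
  }
  invisible(x)
}

#' Predicted response of a fitted 4PL curve
#'
#' @param object A converged [fit_4pl()] result.
#' @param conc Concentrations (>= 0) at which to evaluate the curve.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  stopifnot(object$converged)
  frac <- ifelse(conc == 0, 0,
                 conc^object$hill / (conc^object$hill + object$ic50^object$hill))
  object$top + (object$bottom - object$top) * frac
}

#' Bootstrap confidence interval for the IC50
#'
#' Case-resampling bootstrap, stratified by concentration so every
#' resample retains the dose design: chips are resampled with
#' replacement within each concentration group, the 4PL is refitted,
#' and the percentile interval of log10(IC50) over the converged refits
#' is reported. Deterministic given `seed`. If more than 20% of refits
#' fail a warning notes that the interval may be too wide/unstable.
#'
#' @param fit A converged [fit_4pl()] result.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return The `fit` with `ci_low` / `ci_high` filled in and attributes
#'   `n_failed` (failed refits) and `boot_ic50` (the bootstrap draws).
#' @export
ic50_confidence_interval <- function(fit, n_boot = 1000, seed = 1,
                                     level = 0.95) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  set.seed(seed)
  dat <- fit$data
  groups <- split(seq_len(nrow(dat)), dat$conc)
  draws <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g) {
      g[sample.int(length(g), length(g), replace = TRUE)]
    }), use.names = FALSE)
    bf <- tryCatch(fit_4pl(dat$conc[idx], dat$resp[idx]),
                   error = function(e) NULL)
    if (!is.null(bf) && bf$converged) draws[b] <- log10(bf$ic50)
  }
  n_failed <- sum(is.na(draws))
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf(
      "%d of %d bootstrap refits failed; the interval may be unreliable",
      n_failed, n_boot))
  }
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  fit$ci_low <- 10^qs[1]
  fit$ci_high <- 10^qs[2]
  attr(fit, "n_failed") <- n_failed
  attr(fit, "boot_ic50") <- 10^draws
  fit
}

#' Normalise responses to the untreated-control mean
#'
#' Divides a readout column by the mean of the control group, so the
#' control maps to 1 and a fully inhibiting dose to about 0. The result
#' is unit-free: normalising um and pixel-scaled values gives identical
#' fractions.
#'
#' @param tbl Per-chip metric table (as from [simulate_metric_table()]
#'   or [run_quantify()]).
#' @param readout Column to normalise (default `"distance_um"`).
#' @param control_role Role labelling the control rows (default
#'   `"max_control"`).
#' @return `tbl` with an added `response_fraction` column.
#' @export
normalize_responses <- function(tbl, readout = "distance_um",
                                control_role = "max_control") {
  stopifnot(is.data.frame(tbl), readout %in% names(tbl),
            "role" %in% names(tbl))
  ctrl <- tbl[[readout]][tbl$role == control_role]
  if (length(ctrl) == 0L) {
    stop("no rows with role '", control_role, "' to normalise against")
  }
  m <- mean(ctrl)
  if (!is.finite(m) || m == 0) {
    stop("control mean is zero or non-finite; cannot normalise")
  }
  tbl$response_fraction <- tbl[[readout]] / m
  tbl
}
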