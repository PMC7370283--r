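#' Summary statistics for one control or treatment group
#'
#' Computes the sample mean, sample standard deviation (n - 1 denominator),
#' group size and coefficient of variation of one readout for one group of
#' chips. These are the building blocks of the plate-level performance
#' statistics ([signal_window()], [z_factor()], [assay_variability_ratio()]).
#'
#' @param values Numeric vector of per-chip metric values; at least two
#'   finite values are required.
#' @return An object of class `group_stats`: a list with elements `mean`,
#'   `sd`, `n` and `cv` (`sd/mean`, `NA` when the mean is zero).
#' @examples
#' group_stats(c(8, 12))
#' @export
group_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("group_stats() needs at least 2 finite values, got ", length(values))
  }
  m <- mean(values)
  s <- stats::sd(values)
  group_stats_from_summary(m, s, length(values))
}

#' Build a group_stats object from already-known summary values
#'
#' Useful when only published summary statistics (mean, SD, n) are
#' available rather than per-chip values.
#'
#' @param mean Group mean.
#' @param sd Group sample standard deviation (must be >= 0).
#' @param n Group size (must be >= 2).
#' @return A `group_stats` object; see [group_stats()].
#' @export
group_stats_from_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 2)
  structure(
    list(mean = mean, sd = sd, n = as.integer(n),
         cv = if (mean != 0) sd / mean else NA_real_),
    class = "group_stats"
  )
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group_stats: mean %.4g, sd %.4g, n %d, cv %.3g\n",
              x$mean, x$sd, x$n,
              if (is.na(x$cv)) NA_real_ else x$cv))
  invisible(x)
}

# standard error of the mean used by the guard-banded statistics
.sem <- function(g) g$sd / sqrt(g$n)

#' Signal window of a max/min control pair
#'
#' The signal window measures the separation between the maximum-signal
#' (untreated) and minimum-signal (fully inhibited) control groups after
#' subtracting a 3-standard-error guard band from each, in units of the
#' max-group standard error:
#'
#' \deqn{SW = \frac{(AVG_{max} - 3\,SD_{max}/\sqrt{n_{max}}) -
#'   (AVG_{min} + 3\,SD_{min}/\sqrt{n_{min}})}{SD_{max}/\sqrt{n_{max}}}}
#'
#' Each group uses its own size, so unbalanced control designs (e.g. 15 vs
#' 14 chips) are handled correctly. A negative value means the guard bands
#' overlap: the assay does not separate its controls.
#'
#' @param gmax,gmin `group_stats` for the maximum- and minimum-signal
#'   control groups.
#' @return The signal window (dimensionless scalar).
#' @seealso [z_factor()], [evaluate_acceptance()]
#' @export
signal_window <- function(gmax, gmin) {
  stopifnot(inherits(gmax, "group_stats"), inherits(gmin, "group_stats"))
  if (gmax$sd == 0) {
    stop("signal window is undefined when the max-signal SD is 0")
  }
  ((gmax$mean - 3 * .sem(gmax)) - (gmin$mean + 3 * .sem(gmin))) / .sem(gmax)
}

#' Z-factor (Z') of a max/min control pair
#'
#' Guard-banded group separation normalised by the difference of the group
#' means:
#'
#' \deqn{Z' = \frac{(AVG_{max} - 3\,SD_{max}/\sqrt{n_{max}}) -
#'   (AVG_{min} + 3\,SD_{min}/\sqrt{n_{min}})}{AVG_{max} - AVG_{min}}}
#'
#' Z' is at most 1 and equals 1 only for noise-free controls; values
#' >= 0.4 are conventionally acceptable for complex phenotypic screens.
#' Z' is invariant to rescaling both groups by a common positive factor.
#'
#' @inheritParams signal_window
#' @return The Z-factor (dimensionless scalar, <= 1).
#' @export
z_factor <- function(gmax, gmin) {
  stopifnot(inherits(gmax, "group_stats"), inherits(gmin, "group_stats"))
  sep <- gmax$mean - gmin$mean
  if (sep == 0) {
    stop("Z-factor is undefined when the max- and min-signal means are ",
         "equal (no separation to normalise by)")
  }
  ((gmax$mean - 3 * .sem(gmax)) - (gmin$mean + 3 * .sem(gmin))) / sep
}

#' Assay variability ratio
#'
#' Combined 3-SD spread of both control groups relative to their mean
#' separation:
#'
#' \deqn{AVR = \frac{3\,(SD_{max} + SD_{min})}{AVG_{max} - AVG_{min}}}
#'
#' This complements the Z-factor without the sqrt(n) scaling of the
#' standard error: it equals `1 - Z` for the classic plate-level Z-factor
#' computed from raw SDs. Values below 0.6 are conventionally recommended.
#'
#' @inheritParams signal_window
#' @return The assay variability ratio (dimensionless, >= 0).
#' @export
assay_variability_ratio <- function(gmax, gmin) {
  stopifnot(inherits(gmax, "group_stats"), inherits(gmin, "group_stats"))
  sep <- gmax$mean - gmin$mean
  if (sep == 0) {
    stop("assay variability ratio is undefined when the group means are equal")
  }
  3 * (gmax$sd + gmin$sd) / sep
}

#' Assay performance summary for one readout
#'
#' Bundles the signal window, Z-factor, assay variability ratio and the
#' two control-group coefficients of variation into one record.
#'
#' @inheritParams signal_window
#' @return An object of class `assay_performance`: list with `sw`,
#'   `z_factor`, `avr`, `cv_max`, `cv_min` (both in percent), `sd_max`,
#'   `sd_min`, `n_max`, `n_min`.
#' @export
assay_performance <- function(gmax, gmin) {
  structure(
    list(
      sw = signal_window(gmax, gmin),
      z_factor = z_factor(gmax, gmin),
      avr = assay_variability_ratio(gmax, gmin),
      cv_max = 100 * gmax$cv,
      cv_min = 100 * gmin$cv,
      sd_max = gmax$sd,
      sd_min = gmin$sd,
      n_max = gmax$n,
      n_min = gmin$n
    ),
    class = "assay_performance"
  )
}

#' @export
print.assay_performance <- function(x, ...) {
  cat(sprintf(
    paste0("assay_performance: SW %.2f, Z' %.3f, AVR %.3f, ",
           "CVmax %.1f%%, CVmin %.1f%% (n = %d / %d)\n"),
    x$sw, x$z_factor, x$avr, x$cv_max, x$cv_min, x$n_max, x$n_min))
  invisible(x)
}

#' Screening acceptance flags for one readout
#'
#' Applies the plate acceptance criteria: Z-factor >= 0.4, signal window
#' >= 2, max-signal CV <= 20%, and SDmin <= SDmax for the min-signal
#' group. The overall verdict is the conjunction of the four flags.
#'
#' @param perf An `assay_performance` object (see [assay_performance()]),
#'   or the max-signal `group_stats` (in which case `gmin` must be given
#'   and the performance record is computed first).
#' @param gmin Optional min-signal `group_stats` when `perf` is the
#'   max-signal group.
#' @param z_min,sw_min,cv_max_pct Acceptance thresholds; defaults 0.4, 2
#'   and 20 (percent).
#' @return A list with logical flags `z_ok`, `sw_ok`, `cv_ok`, `sd_ok`
#'   and their conjunction `pass`.
#' @export
evaluate_acceptance <- function(perf, gmin = NULL, z_min = 0.4,
                                sw_min = 2, cv_max_pct = 20) {
  if (inherits(perf, "group_stats")) {
    stopifnot(inherits(gmin, "group_stats"))
    perf <- assay_performance(perf, gmin)
  }
  stopifnot(inherits(perf, "assay_performance"))
  flags <- list(
    z_ok = perf$z_factor >= z_min,
    sw_ok = perf$sw >= sw_min,
    cv_ok = perf$cv_max <= cv_max_pct,
    sd_ok = perf$sd_min <= perf$sd_max
  )
  flags$pass <- flags$z_ok && flags$sw_ok && flags$cv_ok && flags$sd_ok
  flags
}

#' Reconstruct normalised control-group parameters from published
#' performance figures
#'
#' Publications typically report Z', CVmax and CVmin per readout but not
#' the underlying group means and SDs. Fixing the max-signal mean at 1,
#' those three figures plus the group sizes determine the groups exactly:
#' inverting the Z' formula gives
#'
#' \deqn{AVG_{min} = \frac{1 - 3\,cv_{max}/\sqrt{n_{max}} - Z'}
#'   {1 + 3\,cv_{min}/\sqrt{n_{min}} - Z'}}
#'
#' with \eqn{SD_{max} = cv_{max}} and \eqn{SD_{min} = cv_{min} AVG_{min}}.
#' The returned pair reproduces the given Z' and CVs exactly, so
#' recomputing the signal window or variability ratio on it checks the
#' internal consistency of a published performance table.
#'
#' @param z_prime Reported Z-factor.
#' @param cv_max,cv_min Reported coefficients of variation (fractions,
#'   not percent) of the max- and min-signal groups.
#' @param n_max,n_min Group sizes.
#' @return A list with `group_stats` elements `gmax` and `gmin`
#'   (max-signal mean normalised to 1).
#' @examples
#' g <- reconstruct_group_params(0.78, 0.25, 0.70, 15, 14)
#' z_factor(g$gmax, g$gmin)      # returns 0.78
#' signal_window(g$gmax, g$gmin)
#' @export
reconstruct_group_params <- function(z_prime, cv_max, cv_min, n_max, n_min) {
  stopifnot(cv_max >= 0, cv_min >= 0, n_max >= 2, n_min >= 2)
  denom <- 1 + 3 * cv_min / sqrt(n_min) - z_prime
  if (abs(denom) < .Machine$double.eps^0.5) {
    stop("infeasible inputs: Z'-inversion denominator is zero")
  }
  avg_min <- (1 - 3 * cv_max / sqrt(n_max) - z_prime) / denom
  if (!is.finite(avg_min) || avg_min <= 0 || avg_min >= 1) {
    stop(sprintf(
      "infeasible inputs: reconstructed AVGmin = %.4g is not in (0, 1)",
      avg_min))
  }
  list(
    gmax = group_stats_from_summary(1, cv_max, n_max),
    gmin = group_stats_from_summary(avg_min, cv_min * avg_min, n_min)
  )
}
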