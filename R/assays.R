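#' Critical aggregation concentration from a light-scattering dilution series
#'
#' Works in log10-concentration / log10-response space. The pre-CAC regime is
#' a horizontal line (scattering dominated by the solvent); the post-CAC
#' regime is a straight line of positive slope (scattering proportional to
#' aggregate concentration). Every interior split of the sorted series with at
#' least two points on each side is tried exhaustively; each side is fitted by
#' least squares (mean on the left, OLS on the right) and the split with the
#' smallest total residual sum of squares wins. The CAC is the intersection of
#' the two fitted lines, which recovers a noiseless two-regime series exactly.
#'
#' @param series a [concentration_series()] with >= 6 distinct concentrations
#'   spanning >= 1.5 decades. Replicates (same concentration) are averaged.
#' @return a `cac_result` list: `cac` (M), `pre_level` (log10 response
#'   plateau), `post_slope` (log-log slope), `rss`, `n_left`, `n_right`,
#'   `warnings`.
#' @export
fit_cac <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  agg <- stats::aggregate(response ~ concentration, data = series, FUN = mean)
  agg <- agg[order(agg$concentration), ]
  n <- nrow(agg)
  if (n < 6L) {
    abort("need >= 6 distinct concentrations", "mesosaxs_validation_error")
  }
  span <- log10(max(agg$concentration) / min(agg$concentration))
  if (span < 1.5) {
    abort(sprintf("concentration span %.2f decades < 1.5", span),
          "mesosaxs_validation_error")
  }
  if (any(agg$response <= 0)) {
    abort("responses must be > 0 for log-log analysis", "mesosaxs_validation_error")
  }
  x <- log10(agg$concentration)
  y <- log10(agg$response)

  best <- NULL
  any_positive <- FALSE
  for (k in 2L:(n - 2L)) {
    yl <- y[1:k]
    xr <- x[(k + 1L):n]; yr <- y[(k + 1L):n]
    level <- mean(yl)
    fit <- stats::lm.fit(cbind(1, xr), yr)
    slope <- fit$coefficients[[2L]]
    # a numerically-zero slope (flat series) is not aggregation
    if (!is.finite(slope) || slope <= 1e-6) next
    any_positive <- TRUE
    rss <- sum((yl - level)^2) + sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(k = k, level = level, slope = slope,
                   intercept = fit$coefficients[[1L]], rss = rss)
    }
  }
  if (!any_positive || is.null(best)) {
    abort("no split yields a positive post-CAC slope (no aggregation detected)",
          "mesosaxs_no_aggregation_error")
  }

  x_break <- (best$level - best$intercept) / best$slope
  warnings <- character(0)
  if (best$k <= 2L || best$k >= n - 2L) {
    warnings <- c(warnings, "breakpoint at edge of concentration range")
  }
  if (x_break < x[1L] || x_break > x[n]) {
    warnings <- c(warnings, "line intersection outside observed range")
    x_break <- min(max(x_break, x[1L]), x[n])
  }
  for (w in warnings) warn(paste0("fit_cac: ", w), "mesosaxs_unreliable_cac_warning")

  structure(list(cac = 10^x_break,
                 pre_level = best$level,
                 post_slope = best$slope,
                 rss = best$rss,
                 n_left = best$k,
                 n_right = n - best$k,
                 warnings = warnings),
            class = "cac_result")
}

#' @export
print.cac_result <- function(x, ...) {
  cat(sprintf("<cac_result> CAC = %.3g M (plateau 10^%.3g, post-slope %.3g)\n",
              x$cac, x$pre_level, x$post_slope))
  invisible(x)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response on concentration, as used to quantify
#' drug content from HPLC or UV/vis standards.
#'
#' @param standards data.frame with columns `concentration` and `response`;
#'   >= 4 standards over >= 3 distinct concentrations.
#' @return a `calibration_curve` list: `slope`, `intercept`, `r_squared`,
#'   `residual_sd`, `range` (of fitted concentrations).
#' @export
fit_calibration <- function(standards) {
  if (!all(c("concentration", "response") %in% names(standards))) {
    abort("standards needs 'concentration' and 'response' columns",
          "mesosaxs_input_error")
  }
  if (nrow(standards) < 4L || length(unique(standards$concentration)) < 3L) {
    abort("need >= 4 standards over >= 3 distinct concentrations",
          "mesosaxs_input_error")
  }
  fit <- stats::lm(response ~ concentration, data = standards)
  if (anyNA(stats::coef(fit))) {
    abort("singular calibration design", "mesosaxs_input_error")
  }
  smry <- suppressWarnings(summary(fit))  # perfect fits warn in summary.lm
  structure(list(slope = stats::coef(fit)[["concentration"]],
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r_squared = smry$r.squared,
                 residual_sd = smry$sigma,
                 range = range(standards$concentration)),
            class = "calibration_curve")
}

#' Invert a calibration curve to quantify a sample
#'
#' @param calibration a [fit_calibration()] result.
#' @param response measured response(s).
#' @return data.frame with `response`, `concentration`, and `extrapolated`
#'   (TRUE when the implied concentration falls outside the calibrated range).
#' @export
quantify_concentration <- function(calibration, response) {
  stopifnot(inherits(calibration, "calibration_curve"))
  conc <- (response - calibration$intercept) / calibration$slope
  data.frame(response = response, concentration = conc,
             extrapolated = conc < calibration$range[1L] |
                            conc > calibration$range[2L])
}

#' Encapsulation efficiency
#'
#' EE% = 100 * measured / total, where `measured` is the drug quantified in
#' the carrier after free-drug removal and `total` the drug initially added,
#' in the same units. Replicate vectors are averaged with first-order SD
#' propagation.
#'
#' @param measured_drug measured drug amount(s); replicates allowed.
#' @param total_drug total drug amount (scalar or replicates), > 0.
#' @param tolerance allowed relative excess of measured over total before an
#'   inconsistency error (default 0.05; measurement noise can push EE%
#'   slightly past 100).
#' @return list with `ee_percent`, `sd` (NA without replicates), `n`.
#' @export
encapsulation_efficiency <- function(measured_drug, total_drug,
                                     tolerance = 0.05) {
  if (any(!is.finite(total_drug)) || any(total_drug <= 0)) {
    abort("total_drug must be > 0", "mesosaxs_validation_error")
  }
  if (any(!is.finite(measured_drug)) || any(measured_drug < 0)) {
    abort("measured_drug must be >= 0", "mesosaxs_validation_error")
  }
  m <- mean(measured_drug)
  t <- mean(total_drug)
  sd_m <- if (length(measured_drug) > 1L) stats::sd(measured_drug) else 0
  if (m > t * (1 + tolerance) + sd_m) {
    abort("measured drug exceeds total beyond stated uncertainty",
          "mesosaxs_inconsistency_error")
  }
  ee <- 100 * m / t
  sd_ee <- if (length(measured_drug) > 1L) 100 * sd_m / t else NA_real_
  list(ee_percent = ee, sd = sd_ee, n = length(measured_drug))
}

#' Cumulative in-vitro release with sampling correction
#'
#' Dialysis-release bookkeeping for the withdraw-and-replace sampling scheme:
#' at each timepoint an aliquot is removed from the medium and replaced with
#' fresh buffer, so the analyte mass released by step n is
#' \deqn{M_n = C_n V_{medium} + \sum_{i<n} C_i V_{aliquot}.}
#'
#' @param samples data.frame with columns `time` (h, strictly increasing) and
#'   `concentration` (mass/volume in the medium at sampling), plus optional
#'   `replicate` (averaged per time with SD reported).
#' @param volumes list with `medium` and `aliquot` (same volume unit as the
#'   concentrations' denominator); `aliquot < medium`.
#' @param total_loaded total analyte mass loaded (same mass unit).
#' @param tolerance allowed overshoot of 100% before a mass-balance error, in
#'   percentage points (default 1).
#' @return a `release_curve` data.frame: `time`, `released_mass`,
#'   `fraction_percent`, `sd_percent`.
#' @export
cumulative_release <- function(samples, volumes, total_loaded, tolerance = 1) {
  if (!all(c("time", "concentration") %in% names(samples))) {
    abort("samples needs 'time' and 'concentration' columns",
          "mesosaxs_input_error")
  }
  if (!is.finite(total_loaded) || total_loaded <= 0) {
    abort("total_loaded must be > 0", "mesosaxs_validation_error")
  }
  vm <- volumes$medium; va <- volumes$aliquot
  if (!is.finite(vm) || !is.finite(va) || vm <= 0 || va < 0 || va >= vm) {
    abort("need 0 <= aliquot < medium", "mesosaxs_validation_error")
  }
  if (!is.null(samples$replicate)) {
    sdt <- stats::aggregate(concentration ~ time, data = samples, FUN = stats::sd)
    samples <- stats::aggregate(concentration ~ time, data = samples, FUN = mean)
    samples$conc_sd <- sdt$concentration
  }
  samples <- samples[order(samples$time), ]
  if (any(diff(samples$time) <= 0)) {
    abort("times must be strictly increasing", "mesosaxs_validation_error")
  }
  cn <- samples$concentration
  withdrawn <- c(0, cumsum(cn * va)[-length(cn)])
  mass <- cn * vm + withdrawn
  frac <- 100 * mass / total_loaded
  if (any(frac > 100 + tolerance)) {
    abort(sprintf("cumulative release reaches %.1f%% > 100%% + tolerance",
                  max(frac)), "mesosaxs_mass_balance_error")
  }
  sd_pct <- if (!is.null(samples$conc_sd)) {
    100 * samples$conc_sd * vm / total_loaded
  } else {
    rep(NA_real_, length(cn))
  }
  out <- data.frame(time = samples$time, released_mass = mass,
                    fraction_percent = frac, sd_percent = sd_pct)
  class(out) <- c("release_curve", "data.frame")
  out
}
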