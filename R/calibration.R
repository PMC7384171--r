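# Span-offset calibration of isotopologue concentrations against periodic
# three-gas calibration cycles.
#
# The fitted line is true = span * measured + offset (per isotopologue), so
# application is a single affine map. Between successive calibration cycles
# span and offset are interpolated linearly in time; outside the bracketing
# cycles the nearest curve applies.

# nominal validity ranges of the calibrated concentrations (umol/mol)
.cal_valid_range <- function(isotopologue) {
  switch(isotopologue,
         c12 = c(400, 5000),
         c13 = c(4, 50),
         stop("unknown isotopologue: ", isotopologue))
}

#' Derive per-isotopologue true concentrations of calibration gases
#'
#' Calibration gases are specified as total CO2 (umol/mol) plus a known
#' 13C atom fraction; the per-isotopologue true values follow from the
#' two-isotopologue split.
#'
#' @param gases data.frame `gas_id,total_co2_ppm,atom_fraction_13C`.
#' @return The input with `true_c12` and `true_c13` columns added.
#' @export
calibration_gas_truth <- function(gases) {
  stopifnot(all(c("gas_id", "total_co2_ppm", "atom_fraction_13C") %in% names(gases)))
  gases$true_c13 <- gases$total_co2_ppm * gases$atom_fraction_13C
  gases$true_c12 <- gases$total_co2_ppm * (1 - gases$atom_fraction_13C)
  gases
}

#' Fit a span-offset calibration line for one isotopologue
#'
#' Ordinary least squares of true on measured concentration across the
#' calibration gases: true = span * measured + offset. With exactly two gas
#' levels the line interpolates and `residual_sd` is 0.
#'
#' @param measured Measured mean concentrations (umol/mol), one per gas.
#' @param true Known true concentrations (umol/mol).
#' @param isotopologue `"c12"` or `"c13"`.
#' @param fit_time Timestamp attached to the fit (cycle midpoint).
#' @return One-row data.frame (a CalibrationCurve): `isotopologue`, `span`,
#'   `offset`, `fit_time`, `range_lo`, `range_hi`, `residual_sd`, `n`.
#' @export
fit_span_offset <- function(measured, true, isotopologue = c("c12", "c13"),
                            fit_time = NA) {
  isotopologue <- match.arg(isotopologue)
  stopifnot(length(measured) == length(true), length(measured) >= 2)
  if (length(unique(measured)) < 2) {
    stop("fit_span_offset: identical measured values at different true values (singular fit)")
  }
  fit <- stats::lm(true ~ measured)
  span <- unname(stats::coef(fit)[2])
  offset <- unname(stats::coef(fit)[1])
  if (!is.finite(span) || span <= 0) {
    stop("fit_span_offset: non-positive span (", format(span), ")")
  }
  df_res <- length(measured) - 2
  residual_sd <- if (df_res > 0) sqrt(sum(stats::residuals(fit)^2) / df_res) else 0
  rng <- .cal_valid_range(isotopologue)
  data.frame(isotopologue = isotopologue, span = span, offset = offset,
             fit_time = fit_time, range_lo = rng[1], range_hi = rng[2],
             residual_sd = residual_sd, n = length(measured),
             stringsAsFactors = FALSE)
}

#' Fit calibration curves for every calibration cycle in a stream
#'
#' @param cal_segments Output of [segment_calibration()].
#' @param gases Calibration-gas definitions (see [calibration_gas_truth()]).
#' @return data.frame of CalibrationCurve rows (two per cycle: c12, c13).
#' @export
fit_calibration_cycles <- function(cal_segments, gases) {
  gases <- calibration_gas_truth(gases)
  out <- list()
  for (cy in unique(cal_segments$cycle)) {
    seg <- cal_segments[cal_segments$cycle == cy, , drop = FALSE]
    seg <- merge(seg, gases, by = "gas_id")
    if (nrow(seg) < 2) next
    t_fit <- mean(seg$time)
    out[[length(out) + 1]] <-
      fit_span_offset(seg$c12_mean, seg$true_c12, "c12", t_fit)
    out[[length(out) + 1]] <-
      fit_span_offset(seg$c13_mean, seg$true_c13, "c13", t_fit)
  }
  if (length(out) == 0) stop("fit_calibration_cycles: no usable calibration cycle")
  do.call(rbind, out)
}

#' Apply span-offset calibration to an analyzer stream
#'
#' Corrects each record with span/offset interpolated linearly in time
#' between the bracketing calibration fits (nearest curve outside the
#' bracket). Records farther than `staleness_hours` from any calibration are
#' flagged `flag_uncalibrated` (they are still corrected with the nearest
#' curve). Corrected values outside the isotopologue validity range are
#' flagged `flag_range`. Re-applying calibration to an already-calibrated
#' stream is an error: the affine map is not idempotent.
#'
#' @param records `analyzer_stream` data.frame.
#' @param curves CalibrationCurve table from [fit_calibration_cycles()].
#' @param staleness_hours Maximum tolerated age of the nearest calibration (h).
#' @return The stream with corrected `c12`/`c13`, `calibrated = TRUE`, and
#'   flag columns.
#' @export
apply_calibration <- function(records, curves, staleness_hours = 6) {
  if (any(records$calibrated)) {
    stop("apply_calibration: stream already calibrated (double application)")
  }
  tt <- as.numeric(records$time)
  out <- records
  out$flag_range <- FALSE
  nearest_gap <- rep(Inf, nrow(records))
  for (iso in c("c12", "c13")) {
    cv <- curves[curves$isotopologue == iso, , drop = FALSE]
    if (nrow(cv) == 0) stop("apply_calibration: no curves for ", iso)
    cv <- cv[order(cv$fit_time), , drop = FALSE]
    ft <- as.numeric(cv$fit_time)
    if (nrow(cv) == 1) {
      span <- rep(cv$span, length(tt)); offset <- rep(cv$offset, length(tt))
    } else {
      span <- stats::approx(ft, cv$span, xout = tt, rule = 2)$y
      offset <- stats::approx(ft, cv$offset, xout = tt, rule = 2)$y
    }
    corrected <- span * out[[iso]] + offset
    rng <- .cal_valid_range(iso)
    out$flag_range <- out$flag_range |
      (corrected < rng[1] | corrected > rng[2])
    out[[iso]] <- corrected
    idx <- findInterval(tt, ft)
    lo <- ft[pmax(idx, 1)]
    hi <- ft[pmin(idx + 1, length(ft))]
    gap <- pmin(abs(tt - lo), abs(tt - hi))
    nearest_gap <- pmin(nearest_gap, gap)
  }
  out$flag_uncalibrated <- nearest_gap > staleness_hours * 3600
  out$flag_negative <- out$c12 < 0 | out$c13 < 0
  out$calibrated <- TRUE
  out
}
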