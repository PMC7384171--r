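# Flux and isotope-mixing equations with first-order Taylor uncertainty
# propagation and coefficient-of-variation quality control.
#
# Soil respiration of a steady-state flow-through chamber:
#   SR = f_molar * (CO2_out - CO2_in) / A        [umol CO2 m-2 s-1]
# with total CO2 = c12 + c13 (umol/mol), f_molar the volumetric flow
# converted to mol/s at the reference conditions of the mass-flow meter.
#
# Two-member mixing gives the atom fraction of the respired source:
#   chi_SR = (chi_out*CO2_out - chi_in*CO2_in) / (CO2_out - CO2_in)
#          = (c13_out - c13_in) / (CO2_out - CO2_in)
# the excess above the pre-label natural abundance is
#   chiE = chi_SR - chi_NA
# and the absolute tracer efflux
#   abs13C = chiE * SR * M(13C) * 3600 / 1000    [mg 13C m-2 hr-1].
#
# All uncertainties assume independent inputs (covariances set to zero).

#' Atom fraction of 13CO2
#'
#' chi = c13 / (c13 + c12). Returns NA (flagged undefined) where the total is
#' not positive.
#'
#' @param c13,c12 Isotopologue concentrations (umol/mol).
#' @return Atom fraction in \[0, 1\].
#' @export
#' @examples
#' atom_fraction(4.4, 395.6) # 0.011
atom_fraction <- function(c13, c12) {
  total <- c13 + c12
  out <- ifelse(total > 0, c13 / total, NA_real_)
  out
}

#' Soil respiration flux of chamber measurements
#'
#' Applies the steady-state flow-through chamber equation to each measurement
#' row and propagates the window standard deviations of the concentration
#' summaries and the flow by first-order Taylor expansion.
#'
#' @param meas ChamberMeasurement data.frame (see [segment_stream()]).
#' @param area Chamber footprint (m2).
#' @param temperature,pressure Reference conditions of the flow meter
#'   (K, kPa); default 273.15 K / 101.325 kPa.
#' @return `meas` with columns `co2_in`, `co2_in_sd`, `co2_out`, `co2_out_sd`,
#'   `sr` (umol m-2 s-1), `sr_sd` added.
#' @export
compute_sr <- function(meas, area, temperature = 273.15, pressure = 101.325) {
  stopifnot(area > 0)
  co2_in <- meas$inlet12_mean + meas$inlet13_mean
  co2_out <- meas$outlet12_mean + meas$outlet13_mean
  co2_in_sd <- sqrt(meas$inlet12_sd^2 + meas$inlet13_sd^2)
  co2_out_sd <- sqrt(meas$outlet12_sd^2 + meas$outlet13_sd^2)
  fm <- .molar_flow(meas$flow_mean, temperature, pressure)
  fm_sd <- .molar_flow(meas$flow_sd, temperature, pressure)
  delta <- co2_out - co2_in
  sr <- fm * delta / area
  # partials: dSR/df = delta/area, dSR/dCO2_out = fm/area, dSR/dCO2_in = -fm/area
  sr_sd <- sqrt((delta / area * fm_sd)^2 +
                  (fm / area)^2 * (co2_out_sd^2 + co2_in_sd^2))
  bad <- !is.finite(meas$flow_mean) | meas$flow_mean <= 0
  sr[bad] <- NA_real_
  sr_sd[bad] <- NA_real_
  meas$co2_in <- co2_in
  meas$co2_in_sd <- co2_in_sd
  meas$co2_out <- co2_out
  meas$co2_out_sd <- co2_out_sd
  meas$sr <- sr
  meas$sr_sd <- sr_sd
  meas
}

#' Source atom fraction of soil respiration (two-member mixing)
#'
#' Solves the two-member mixing balance for the isotopic composition of the
#' respired CO2 added between chamber inlet and outlet. The propagated sd
#' covers the four concentration summaries (inlet/outlet x isotopologue).
#' Measurements whose inlet-outlet gradient is below `min_gradient` are
#' marked invalid rather than allowed to blow up the division; results
#' outside the sanity interval \[-0.1, 1.1\] are flagged.
#'
#' @param meas Output of [compute_sr()].
#' @param min_gradient Minimum |CO2_out - CO2_in| (umol/mol) for the mixing
#'   equation to be attempted.
#' @return `meas` with `chi_sr`, `chi_sr_sd`, `chi_in`, `chi_out`,
#'   `chi_flag` added.
#' @export
source_atom_fraction <- function(meas, min_gradient = 5) {
  num <- meas$outlet13_mean - meas$inlet13_mean
  den <- meas$co2_out - meas$co2_in
  ok <- is.finite(den) & abs(den) >= min_gradient
  chi <- ifelse(ok, num / den, NA_real_)
  # chi = (o13 - i13)/D with D = (o12 + o13) - (i12 + i13)
  d_o13 <- (den - num) / den^2
  d_i13 <- (num - den) / den^2
  d_o12 <- -num / den^2
  d_i12 <- num / den^2
  sd <- sqrt((d_o13 * meas$outlet13_sd)^2 + (d_i13 * meas$inlet13_sd)^2 +
               (d_o12 * meas$outlet12_sd)^2 + (d_i12 * meas$inlet12_sd)^2)
  sd[!ok] <- NA_real_
  meas$chi_in <- atom_fraction(meas$inlet13_mean, meas$inlet12_mean)
  meas$chi_out <- atom_fraction(meas$outlet13_mean, meas$outlet12_mean)
  meas$chi_sr <- chi
  meas$chi_sr_sd <- sd
  meas$chi_flag <- ifelse(!ok, "gradient_below_minimum",
                          ifelse(chi < -0.1 | chi > 1.1, "outside_sanity", "ok"))
  meas
}

#' Natural-abundance baseline of soil-respired 13C
#'
#' Mean source atom fraction over the valid pre-label observations of one
#' monolith (default: everything within `window_hours` before `label_start`).
#' With a single observation its propagated sd is used; with several, the
#' between-observation sd. Natural abundance is never defaultable: an empty
#' window is a hard error.
#'
#' @param obs Flux observation rows of one monolith (needs `t_mid`, `chi_sr`,
#'   `chi_sr_sd`, `chi_flag`).
#' @param label_start POSIXct start of the labelling.
#' @param window_hours Look-back window before `label_start` (h).
#' @return list(`chi_na`, `chi_na_sd`, `n`).
#' @export
estimate_natural_abundance <- function(obs, label_start, window_hours = 48) {
  sel <- obs$t_mid < label_start &
    obs$t_mid >= label_start - window_hours * 3600 &
    is.finite(obs$chi_sr) & obs$chi_flag == "ok"
  v <- obs$chi_sr[sel]
  if (length(v) == 0) {
    stop("estimate_natural_abundance: no valid pre-label observation")
  }
  sd <- if (length(v) > 1) stats::sd(v) else obs$chi_sr_sd[sel]
  list(chi_na = mean(v), chi_na_sd = sd, n = length(v))
}

#' Excess atom fraction above natural abundance
#'
#' chiE = chi_SR - chi_NA. Negative values (noise around zero) are retained
#' here; the negativity exclusion is applied downstream by [qc_filter()].
#'
#' @param chi_sr,chi_sr_sd Source atom fraction and sd.
#' @param chi_na,chi_na_sd Natural-abundance baseline and sd.
#' @return list(`chi_excess`, `chi_excess_sd`).
#' @export
excess_atom_fraction <- function(chi_sr, chi_sr_sd, chi_na, chi_na_sd = 0) {
  if (any(!is.finite(chi_na))) {
    stop("excess_atom_fraction: missing natural abundance")
  }
  list(chi_excess = chi_sr - chi_na,
       chi_excess_sd = sqrt(chi_sr_sd^2 + chi_na_sd^2))
}

#' Absolute tracer efflux in soil respiration
#'
#' abs13C = chiE * SR, converted from umol 13C m-2 s-1 to mg 13C m-2 hr-1
#' with M(13C) = 13.00335 g/mol. Covariance between SR and chiE is set to
#' zero in the propagation.
#'
#' @param chi_excess,chi_excess_sd Excess atom fraction and sd.
#' @param sr,sr_sd Soil respiration (umol m-2 s-1) and sd.
#' @return list(`abs13c`, `abs13c_sd`) in mg 13C m-2 hr-1.
#' @export
tracer_flux <- function(chi_excess, chi_excess_sd, sr, sr_sd) {
  conv <- .M13 * 3600 / 1000 # umol m-2 s-1 -> mg m-2 hr-1
  list(abs13c = chi_excess * sr * conv,
       abs13c_sd = conv * sqrt((chi_excess * sr_sd)^2 + (sr * chi_excess_sd)^2))
}

#' Quality-control filter on flux observations
#'
#' Applies the exclusion rules: observations with SR < 0 or chiE < 0 are
#' `excluded_negative`; observations with CV(SR) > 1 or CV(chiE) > 1 are
#' `excluded_cv` (the boundary CV = 1 is retained). Observations whose inputs
#' were invalid (no flow, gradient below minimum, empty windows) are
#' `invalid_input`. CVs are the ratio of propagated sd to value, defined
#' where the value is positive.
#'
#' @param obs Flux table with `sr`, `sr_sd`, `chi_excess`, `chi_excess_sd`
#'   (the excess columns may be absent pre-label).
#' @return `obs` with `cv_sr`, `cv_excess` and `qc` columns set.
#' @export
qc_filter <- function(obs) {
  has_excess <- "chi_excess" %in% names(obs) && any(is.finite(obs$chi_excess))
  obs$cv_sr <- ifelse(is.finite(obs$sr) & obs$sr > 0, obs$sr_sd / obs$sr, NA_real_)
  if (has_excess) {
    obs$cv_excess <- ifelse(is.finite(obs$chi_excess) & obs$chi_excess > 0,
                            obs$chi_excess_sd / obs$chi_excess, NA_real_)
  } else {
    obs$cv_excess <- NA_real_
  }
  invalid <- !is.finite(obs$sr) |
    (!is.null(obs$chi_flag) & obs$chi_flag == "gradient_below_minimum")
  negative <- !invalid & (obs$sr < 0 |
                            (has_excess & is.finite(obs$chi_excess) & obs$chi_excess < 0))
  high_cv <- !invalid & !negative &
    ((is.finite(obs$cv_sr) & obs$cv_sr > 1) |
       (is.finite(obs$cv_excess) & obs$cv_excess > 1))
  obs$qc <- ifelse(invalid, "invalid_input",
                   ifelse(negative, "excluded_negative",
                          ifelse(high_cv, "excluded_cv", "ok")))
  obs
}

#' Full flux computation for a measurement table
#'
#' Convenience wrapper running [compute_sr()], [source_atom_fraction()],
#' per-monolith natural-abundance estimation, [excess_atom_fraction()],
#' [tracer_flux()] and [qc_filter()].
#'
#' @param meas ChamberMeasurement table.
#' @param meta Monolith metadata (needs `monolith_id`, `label_start`).
#' @param area Chamber footprint (m2).
#' @param min_gradient Passed to [source_atom_fraction()].
#' @param na_window_hours Passed to [estimate_natural_abundance()].
#' @param temperature,pressure Flow reference conditions.
#' @return list(`fluxes` = FluxObservation table, `chi_na` = per-monolith
#'   baseline table).
#' @export
compute_fluxes <- function(meas, meta, area,
                           min_gradient = 5, na_window_hours = 48,
                           temperature = 273.15, pressure = 101.325) {
  obs <- compute_sr(meas, area, temperature, pressure)
  obs <- source_atom_fraction(obs, min_gradient)
  obs$chi_excess <- NA_real_
  obs$chi_excess_sd <- NA_real_
  na_rows <- list()
  for (m in unique(obs$monolith_id)) {
    i <- obs$monolith_id == m
    ls <- meta$label_start[match(m, meta$monolith_id)]
    if (is.na(ls)) next
    na_est <- estimate_natural_abundance(obs[i, , drop = FALSE], ls,
                                         na_window_hours)
    ex <- excess_atom_fraction(obs$chi_sr[i], obs$chi_sr_sd[i],
                               na_est$chi_na, na_est$chi_na_sd)
    obs$chi_excess[i] <- ex$chi_excess
    obs$chi_excess_sd[i] <- ex$chi_excess_sd
    na_rows[[m]] <- data.frame(monolith_id = m, chi_na = na_est$chi_na,
                               chi_na_sd = na_est$chi_na_sd, n = na_est$n,
                               stringsAsFactors = FALSE)
  }
  tf <- tracer_flux(obs$chi_excess, obs$chi_excess_sd, obs$sr, obs$sr_sd)
  obs$abs13c <- tf$abs13c
  obs$abs13c_sd <- tf$abs13c_sd
  obs <- qc_filter(obs)
  list(fluxes = obs, chi_na = do.call(rbind, na_rows))
}
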