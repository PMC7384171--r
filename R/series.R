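# Temporal alignment and cumulation of irregular per-monolith flux series.
#
# Irregular observations are smoothed with a penalized cubic spline and
# predicted on a common regular grid (default 2 h step). Grid points inside
# observation gaps longer than max_gap (default 6 h, boundary inclusive) are
# masked: splines are not trusted to extrapolate across long gaps. Cumulation
# follows the trapezoid rule, bridging masked runs linearly; an alternative
# replicate-mean rule fills a gap with the mean cumulative increment of the
# other replicates. Uncertainty of cumulative totals comes from Monte-Carlo
# resampling of the gridded points.

#' Fit a light smoothing spline to an irregular series
#'
#' Penalized cubic smoothing spline (near-interpolating at the default
#' smoothing). With fewer than 4 observations the series is passed through as
#' linear interpolation and flagged.
#'
#' @param time_h Observation times (hours, numeric).
#' @param value Observed values.
#' @param spar Smoothing parameter of [stats::smooth.spline()]; default 0.05
#'   (light smoothing).
#' @param ... Further arguments to [stats::smooth.spline()] (e.g. `lambda`
#'   to set the roughness penalty directly).
#' @return An object of class `flux_spline` with `$predict(t)`, `$method`
#'   (`"spline"` or `"linear"`), `$n`.
#' @export
fit_smoothing_spline <- function(time_h, value, spar = 0.05, ...) {
  keep <- is.finite(time_h) & is.finite(value)
  time_h <- time_h[keep]
  value <- value[keep]
  o <- order(time_h)
  time_h <- time_h[o]
  value <- value[o]
  if (length(unique(time_h)) < 4) {
    warning("fit_smoothing_spline: < 4 observations; falling back to linear interpolation")
    obj <- list(
      predict = function(t) stats::approx(time_h, value, xout = t, rule = 2)$y,
      method = "linear", n = length(time_h)
    )
  } else {
    args <- list(x = time_h, y = value, keep.data = FALSE, ...)
    if (!"lambda" %in% names(args)) args$spar <- spar
    fit <- do.call(stats::smooth.spline, args)
    obj <- list(
      predict = function(t) stats::predict(fit, t)$y,
      method = "spline", n = length(time_h)
    )
  }
  class(obj) <- "flux_spline"
  obj
}

#' Resample a fitted series onto a regular grid with gap masking
#'
#' Emits spline predictions at grid times supported by observations: a grid
#' point is masked when it falls outside the observed time span or inside an
#' observation gap longer than `max_gap` (a gap of exactly `max_gap` is
#' filled). The per-point sd is taken from the nearest observation: the
#' spline smooths values, not uncertainties.
#'
#' @param fit A `flux_spline` from [fit_smoothing_spline()].
#' @param obs_time_h,obs_sd Observation times (h) and their sds.
#' @param step Grid step (h), default 2.
#' @param max_gap Maximum observation gap the spline may fill (h), default 6.
#' @param origin Grid phase: grid times are multiples of `step` offset from
#'   `origin` (h), default 0.
#' @return A FluxSeries data.frame: `time_h`, `value`, `sd`, `mask`
#'   (`"observed"` or `"masked"`).
#' @export
resample_to_grid <- function(fit, obs_time_h, obs_sd = NULL,
                             step = 2, max_gap = 6, origin = 0) {
  obs_time_h <- sort(obs_time_h[is.finite(obs_time_h)])
  stopifnot(length(obs_time_h) >= 2)
  lo <- origin + ceiling((min(obs_time_h) - origin) / step) * step
  hi <- origin + floor((max(obs_time_h) - origin) / step) * step
  grid <- seq(lo, hi, by = step)
  # bracketing observations around each grid point
  idx <- findInterval(grid, obs_time_h)
  prev <- obs_time_h[pmax(idx, 1)]
  nxt <- obs_time_h[pmin(idx + 1, length(obs_time_h))]
  on_obs <- idx >= 1 & grid == prev
  gap <- ifelse(on_obs, 0, nxt - prev)
  masked <- idx < 1 | gap > max_gap
  value <- rep(NA_real_, length(grid))
  value[!masked] <- fit$predict(grid[!masked])
  sd <- rep(NA_real_, length(grid))
  if (!is.null(obs_sd)) {
    near <- vapply(grid, function(g) which.min(abs(obs_time_h - g)), integer(1))
    sd <- obs_sd[near]
    sd[masked] <- NA_real_
  }
  data.frame(time_h = grid, value = value, sd = sd,
             mask = ifelse(masked, "masked", "observed"),
             stringsAsFactors = FALSE)
}

# Linear-functional weights of the trapezoid integral over [a, b] with
# masked runs bridged linearly between flanking unmasked points. Returns the
# weight of each usable (unmasked or replicate-filled) point, plus the
# integration bounds actually used and the gap-filled time share.
.trapz_weights <- function(series, window) {
  a <- window[1]; b <- window[2]
  sel <- series$time_h >= a & series$time_h <= b
  s <- series[sel, , drop = FALSE]
  usable <- s$mask %in% c("observed", "gap-filled-replicate")
  if (sum(usable) < 2) {
    stop("cumulate_trapezoid: fewer than 2 unmasked grid points in window")
  }
  tu <- s$time_h[usable]
  m <- length(tu)
  # Trapezoid over the usable points IS linear bridging of interior masked
  # runs; the integral is the fixed linear functional sum(w * value) with the
  # classic trapezoid weights on the (possibly gappy) abscissae.
  dts <- diff(tu)
  w <- c(dts[1] / 2,
         if (m > 2) (tu[3:m] - tu[1:(m - 2)]) / 2 else NULL,
         dts[m - 1] / 2)
  h <- stats::median(diff(s$time_h))
  filled_time <- sum(dts[dts > h + 1e-9]) +
    h * sum(s$mask == "gap-filled-replicate")
  list(time_h = tu, weights = w, span = c(min(tu), max(tu)),
       filled_time = filled_time,
       replicate_filled = sum(s$mask == "gap-filled-replicate"),
       values = s$value[usable], sds = s$sd[usable],
       window = c(a, b))
}

#' Cumulative flux over a window by the trapezoid rule
#'
#' Integrates the gridded series over `window`, bridging interior masked runs
#' linearly between the flanking unmasked points. Leading/trailing masked
#' points (no flanking support) are dropped: the integral covers the first to
#' the last supported grid point inside the window. `fill_fraction` reports
#' the share of the window covered by gap-filled cells or uncovered edges.
#'
#' @param series FluxSeries data.frame from [resample_to_grid()].
#' @param window Numeric `c(start, end)` in grid hours.
#' @return One-row data.frame (a CumulativeFlux): `window_start`,
#'   `window_end`, `total` (value units x hours), `fill_fraction`,
#'   `n_points`.
#' @export
cumulate_trapezoid <- function(series, window) {
  w <- .trapz_weights(series, window)
  total <- sum(w$weights * w$values)
  uncovered <- (w$span[1] - w$window[1]) + (w$window[2] - w$span[2])
  fill_fraction <- min(1, (w$filled_time + uncovered) / diff(w$window))
  data.frame(window_start = w$window[1], window_end = w$window[2],
             total = total, fill_fraction = fill_fraction,
             n_points = length(w$weights))
}

#' Fill a masked gap with the replicate-mean cumulative increment
#'
#' For each masked run of the target series overlapping `gap`, computes each
#' replicate's cumulative increment over the run (flank to flank) and sets
#' the target's masked points to the constant level that reproduces the mean
#' replicate increment exactly under the trapezoid rule. Filled points are
#' marked `"gap-filled-replicate"`. If no replicate covers a run, it is left
#' masked with a warning.
#'
#' @param target FluxSeries to fill.
#' @param replicates List of FluxSeries of the other replicates (same grid).
#' @param gap Numeric `c(start, end)` window (h) containing the gap(s).
#' @return The target FluxSeries with filled points.
#' @export
replicate_mean_infill <- function(target, replicates, gap) {
  stopifnot(length(replicates) >= 1)
  masked <- which(target$mask == "masked" &
                    target$time_h >= gap[1] & target$time_h <= gap[2])
  if (length(masked) == 0) return(target)
  runs <- split(masked, cumsum(c(1, diff(masked) != 1)))
  h <- stats::median(diff(target$time_h))
  for (run in runs) {
    lo <- min(run) - 1
    hi <- max(run) + 1
    if (lo < 1 || hi > nrow(target) ||
        target$mask[lo] != "observed" || target$mask[hi] != "observed") {
      warning("replicate_mean_infill: gap run without unmasked flanks; left masked")
      next
    }
    t_lo <- target$time_h[lo]
    t_hi <- target$time_h[hi]
    incr <- vapply(replicates, function(r) {
      ok <- r$mask == "observed" & is.finite(r$value)
      if (!any(ok & r$time_h <= t_lo) || !any(ok & r$time_h >= t_hi)) {
        return(NA_real_)
      }
      tryCatch(cumulate_trapezoid(r, c(t_lo, t_hi))$total,
               error = function(e) NA_real_)
    }, numeric(1))
    incr <- incr[is.finite(incr)]
    if (length(incr) == 0) {
      warning("replicate_mean_infill: no replicate covers gap [",
              t_lo, ", ", t_hi, "] h; left masked")
      next
    }
    m_incr <- mean(incr)
    k <- length(run)
    a <- target$value[lo]
    b <- target$value[hi]
    # constant level v at the k interior points making the trapezoid integral
    # over [t_lo, t_hi] equal the mean replicate increment:
    # integral = h * ((a + b)/2 + k*v)
    v <- (m_incr / h - (a + b) / 2) / k
    target$value[run] <- v
    target$sd[run] <- if (length(incr) > 1) {
      stats::sd(incr) / (diff(c(t_lo, t_hi)))
    } else {
      mean(target$sd[c(lo, hi)], na.rm = TRUE)
    }
    target$mask[run] <- "gap-filled-replicate"
  }
  target
}

#' Monte-Carlo uncertainty of a cumulative total
#'
#' Draws `n` resampled series with each usable grid point independently
#' normal(value, sd), integrates each with the same bridged trapezoid rule,
#' and reports the sd and central 95% interval of the totals. The bridged
#' trapezoid integral is a fixed linear functional of the usable points, so
#' draws reduce to a weighted sum.
#'
#' @param series FluxSeries data.frame (per-point sds required).
#' @param window Numeric `c(start, end)` (h).
#' @param n Number of Monte-Carlo draws, default 1000.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return list(`mc_sd`, `mc_lo`, `mc_hi`, `totals`).
#' @export
mc_cumulative_uncertainty <- function(series, window, n = 1000, seed = NULL) {
  w <- .trapz_weights(series, window)
  sds <- ifelse(is.finite(w$sds), w$sds, 0)
  totals <- .with_seed(seed, {
    m <- length(w$values)
    draws <- matrix(stats::rnorm(n * m, mean = rep(w$values, each = n),
                                 sd = rep(sds, each = n)), nrow = n)
    as.numeric(draws %*% w$weights)
  })
  qs <- stats::quantile(totals, c(0.025, 0.975), names = FALSE)
  list(mc_sd = stats::sd(totals), mc_lo = qs[1], mc_hi = qs[2],
       totals = totals)
}
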