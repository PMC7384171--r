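# Shared constants and small numeric helpers.

# molar mass of 13C (g/mol)
.M13 <- 13.00335

#' Molar volume of an ideal gas at reference conditions
#'
#' Mass-flow meters report volumetric flow at fixed reference conditions; this
#' converts that convention into the molar volume used to turn ml/min into
#' mol/s. Default is 0 degC / 101.325 kPa (22.414 L/mol).
#'
#' @param temperature Reference temperature (K).
#' @param pressure Reference pressure (kPa).
#' @return Molar volume in L/mol.
#' @export
molar_volume <- function(temperature = 273.15, pressure = 101.325) {
  22.414 * (temperature / 273.15) * (101.325 / pressure)
}

# volumetric flow (ml/min) -> molar flow (mol/s)
.molar_flow <- function(flow_ml_min, temperature = 273.15, pressure = 101.325) {
  flow_ml_min / 1000 / molar_volume(temperature, pressure) / 60
}

#' Trapezoid-rule integral of sampled values
#'
#' @param x Ordered abscissae.
#' @param y Values at `x`.
#' @return The trapezoid-rule integral.
#' @export
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (is.unsorted(x)) stop("trapz: x must be non-decreasing")
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hours between two POSIXct times (or numeric pass-through)
.hours_since <- function(time, origin) {
  as.numeric(difftime(time, origin, units = "hours"))
}

#' First-order Taylor (delta-method) standard deviation
#'
#' Propagates independent input uncertainties through a differentiable
#' function using its closed-form partial derivatives:
#' sd = sqrt(sum((dg/dx_i)^2 * sd_i^2)).
#'
#' @param partials Numeric vector of partial derivatives evaluated at the
#'   input values.
#' @param sds Numeric vector of input standard deviations (same length).
#' @return Propagated standard deviation.
#' @export
#' @examples
#' taylor_sd(c(2, -1), c(0.1, 0.3))
taylor_sd <- function(partials, sds) {
  stopifnot(length(partials) == length(sds))
  if (any(sds < 0, na.rm = TRUE)) stop("taylor_sd: negative input sd")
  if (any(!is.finite(partials))) stop("taylor_sd: partial undefined at evaluation point")
  sqrt(sum((partials * sds)^2))
}
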