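# Back-diffusion kinetics of the dark-labelling test, and conversion of
# cumulative tracer effluxes into fractions of assimilated 13C with
# treatment-level summaries.

#' Fit a single-exponential decay to a tracer efflux series
#'
#' Nonlinear least squares of r(t) = r0 * exp(-k t), initialized from a
#' log-linear regression on the positive values. The mean residence time of
#' the physically back-diffusing tracer is MRT = 1/k. A series that does not
#' decay (k <= 0) raises a condition of class `isopulse_decay_error` carrying
#' the log-linear fallback estimate in its `fallback` field.
#'
#' @param time_min Times (minutes) since the pulse.
#' @param value Tracer efflux (e.g. mg 13C m-2 hr-1).
#' @return An object of class `decay_fit`: list(`r0`, `k` (1/min),
#'   `mrt_min`, `rss`, `n`).
#' @export
fit_exponential_decay <- function(time_min, value) {
  keep <- is.finite(time_min) & is.finite(value)
  time_min <- time_min[keep]
  value <- value[keep]
  if (length(value) < 5) stop("fit_exponential_decay: fewer than 5 points")
  pos <- value > 0
  if (mean(pos) < 0.5) stop("fit_exponential_decay: positive values must dominate")
  ll <- stats::lm(log(value[pos]) ~ time_min[pos])
  k0 <- -unname(stats::coef(ll)[2])
  r0_0 <- exp(unname(stats::coef(ll)[1]))
  fail <- function(msg, k_est, r0_est) {
    stop(structure(
      list(message = paste0("fit_exponential_decay: ", msg,
                            " (log-linear fallback: r0 = ", signif(r0_est, 6),
                            ", k = ", signif(k_est, 6), " /min)"),
           call = NULL,
           fallback = list(r0 = r0_est, k = k_est)),
      class = c("isopulse_decay_error", "error", "condition")
    ))
  }
  if (!is.finite(k0) || k0 <= 0) {
    fail("series does not decay (k <= 0)", k0, r0_0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ r0 * exp(-k * time_min),
                      start = list(r0 = r0_0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) fail("nonlinear fit did not converge", k0, r0_0)
  co <- stats::coef(fit)
  if (!is.finite(co[["k"]]) || co[["k"]] <= 0) {
    fail("fitted rate constant not positive", k0, r0_0)
  }
  structure(list(r0 = unname(co[["r0"]]), k = unname(co[["k"]]),
                 mrt_min = 1 / unname(co[["k"]]),
                 rss = sum(stats::residuals(fit)^2), n = length(value)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit: r0 =", signif(x$r0, 4),
      ", k =", signif(x$k, 4), "/min, MRT =", signif(x$mrt_min, 4),
      "min (n =", x$n, ")\n")
  invisible(x)
}

#' Fraction of assimilated tracer respired
#'
#' rel13C = cumulative tracer efflux / total assimilated 13C (both per m2).
#'
#' @param total Cumulative tracer efflux (mg 13C m-2).
#' @param uptake Total assimilated tracer U (mg 13C m-2), > 0.
#' @return Fraction (dimensionless); multiply by 100 for percent.
#' @export
relative_tracer <- function(total, uptake) {
  if (any(!is.finite(uptake)) || any(uptake <= 0)) {
    stop("relative_tracer: uptake U must be present and > 0")
  }
  total / uptake
}

#' Group summaries of cumulative outcomes with drought percent change
#'
#' Means and SDs across replicate monoliths per
#' (land_use, treatment, campaign, window, variable) group, plus the percent
#' change of drought relative to the paired control group,
#' 100 * (1 - drought_mean / control_mean) (positive = reduction under
#' drought).
#'
#' @param cumulatives data.frame with `monolith_id`, `variable`, `window`,
#'   `total` (one row per monolith x variable x window).
#' @param meta Monolith metadata.
#' @return A PartitionSummary data.frame.
#' @export
summarize_groups <- function(cumulatives, meta) {
  d <- merge(cumulatives,
             meta[, c("monolith_id", "land_use", "treatment", "campaign")],
             by = "monolith_id")
  key <- c("variable", "window", "campaign", "land_use", "treatment")
  agg <- stats::aggregate(d$total, d[key], function(x) {
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
      n = length(x))
  })
  out <- cbind(agg[key], as.data.frame(agg$x))
  names(out)[names(out) == "mean"] <- "mean"
  out$percent_change <- NA_real_
  ctrl_key <- c("variable", "window", "campaign", "land_use")
  for (i in which(out$treatment == "drought")) {
    j <- which(out$treatment == "control" &
                 apply(out[ctrl_key], 1, paste, collapse = "\r") ==
                 paste(out[i, ctrl_key], collapse = "\r"))
    if (length(j) == 1 && out$mean[j] != 0) {
      out$percent_change[i] <- 100 * (1 - out$mean[i] / out$mean[j])
    }
  }
  out
}
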