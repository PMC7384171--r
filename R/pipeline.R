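# Raw-to-report orchestration: calibrate -> segment -> flux -> QC -> grid ->
# cumulate -> partition -> stats, with logging, a config snapshot, and
# deterministic re-execution under fixed seeds.

#' Default pipeline configuration
#'
#' Every default is the study-anchored value: 2-h grid step, 6-h maximum
#' spline-filled gap, 120-h post-label and 72-h post-rewetting cumulation
#' windows, 1000 Monte-Carlo draws, light spline smoothing (spar = 0.05),
#' CV > 1 and negativity exclusion, 5 umol/mol minimum chamber gradient,
#' 6-h calibration staleness, 30-s dead band, 5000 permutations.
#'
#' @param ... Overrides of individual fields.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    step_h = 2, max_gap_h = 6,
    window_chase_h = 120, window_rewet_h = 72,
    mc_n = 1000, seed = 1,
    spar = 0.05,
    min_gradient = 5, na_window_h = 48,
    staleness_h = 6, dead_band_s = 30,
    n_perm = 5000,
    temperature = 273.15, pressure = 101.325,
    area = pi * 0.0225^2,
    verbose = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("pipeline_config: unknown field(s) ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Run the full processing pipeline
#'
#' Executes the data-reduction chain on a raw input set (in-memory, as
#' produced by [generate_scenario()], or read from the CSV schemas). Stages:
#' calibration fitting/application, stream segmentation, flux and mixing
#' equations with error propagation, QC exclusion, spline alignment to the
#' common grid, trapezoid cumulation with Monte-Carlo uncertainty and
#' replicate-mean infill of over-long gaps, tracer partitioning, group
#' summaries and (where the design allows) classical plus permutational
#' ANOVA of drought x land use.
#'
#' @param input list with `records` (analyzer_stream), `flow`, `meta`,
#'   `cal_gases`; alternatively named file paths for the same components.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all tables, the log and a
#'   config snapshot are written there.
#' @return list(`measurements`, `fluxes`, `chi_na`, `series`, `cumulatives`,
#'   `summary`, `anova`, `exclusions`, `log`, `config`), class
#'   `isopulse_run`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    log_lines <<- c(log_lines, line)
    if (isTRUE(config$verbose)) message(line)
  }
  if (is.character(input)) {
    input <- list(records = read_analyzer_stream(input[["records"]]),
                  flow = utils::read.csv(input[["flow"]]),
                  meta = read_monolith_meta(input[["meta"]]),
                  cal_gases = utils::read.csv(input[["cal_gases"]]))
    if (!is.null(input$flow$time)) {
      input$flow$time <- as.POSIXct(input$flow$time, tz = "UTC")
    }
  }
  records <- input$records
  meta <- input$meta
  origin <- min(records$time)

  say("calibration: fitting span-offset curves")
  cal_seg <- segment_calibration(records, dead_band = config$dead_band_s)
  if (is.null(cal_seg)) stop("run_pipeline: no calibration cycles in stream")
  curves <- fit_calibration_cycles(cal_seg, input$cal_gases)
  say("calibration: ", nrow(curves) / 2, " cycles fitted")
  records <- apply_calibration(records, curves, config$staleness_h)

  say("segmentation: extracting chamber measurement cycles")
  meas <- segment_stream(records,
                         measurement_protocol(dead_band = config$dead_band_s),
                         flow = input$flow)
  say("segmentation: ", nrow(meas), " cycles, ",
      sum(!meas$valid), " invalid")

  say("flux: applying flux and mixing equations")
  fx <- compute_fluxes(meas[meas$valid, , drop = FALSE], meta,
                       area = config$area,
                       min_gradient = config$min_gradient,
                       na_window_hours = config$na_window_h,
                       temperature = config$temperature,
                       pressure = config$pressure)
  fluxes <- fx$fluxes
  exclusions <- table(factor(fluxes$qc, levels = c(
    "ok", "excluded_negative", "excluded_cv", "invalid_input")))
  say("QC: ", paste(names(exclusions), as.integer(exclusions),
                    sep = "=", collapse = ", "))

  say("grid: spline alignment at ", config$step_h, "-h step")
  label_end_h <- .hours_since(meta$label_end[1], origin)
  rewet_h <- .hours_since(meta$rewetting_time[1], origin)
  windows <- list(chase = c(label_end_h, label_end_h + config$window_chase_h),
                  rewet = c(rewet_h, rewet_h + config$window_rewet_h))
  series <- list()
  for (m in unique(fluxes$monolith_id)) {
    fm <- fluxes[fluxes$monolith_id == m, , drop = FALSE]
    t_h <- .hours_since(fm$t_mid, origin)
    sr_ok <- fm$qc != "invalid_input" & is.finite(fm$sr) & fm$sr >= 0 &
      (!is.finite(fm$cv_sr) | fm$cv_sr <= 1)
    abs_ok <- fm$qc == "ok" &
      t_h >= .hours_since(meta$label_start[match(m, meta$monolith_id)], origin)
    for (v in c("sr", "abs13c")) {
      ok <- if (v == "sr") sr_ok else abs_ok
      if (sum(ok) < 2) {
        say("grid: monolith ", m, " variable ", v, ": too few points, skipped")
        next
      }
      fit <- fit_smoothing_spline(t_h[ok], fm[[v]][ok], spar = config$spar)
      g <- resample_to_grid(fit, t_h[ok], fm[[paste0(v, "_sd")]][ok],
                            step = config$step_h, max_gap = config$max_gap_h)
      g$monolith_id <- m
      g$variable <- v
      series[[paste(m, v)]] <- g
    }
  }

  say("infill: replicate-mean rule for over-long gaps")
  for (key in names(series)) {
    s <- series[[key]]
    if (!any(s$mask == "masked")) next
    m <- s$monolith_id[1]
    v <- s$variable[1]
    grp <- meta[meta$monolith_id == m, ]
    sib <- meta$monolith_id[meta$land_use == grp$land_use &
                              meta$treatment == grp$treatment &
                              meta$campaign == grp$campaign &
                              meta$monolith_id != m]
    reps <- series[paste(sib, v)]
    reps <- reps[!vapply(reps, is.null, logical(1))]
    if (length(reps) == 0) next
    for (w in windows) {
      if (any(s$mask == "masked" & s$time_h >= w[1] & s$time_h <= w[2])) {
        s <- withCallingHandlers(
          replicate_mean_infill(s, reps, w),
          warning = function(cond) {
            say("infill: ", conditionMessage(cond))
            invokeRestart("muffleWarning")
          })
      }
    }
    series[[key]] <- s
  }

  say("cumulate: trapezoid integrals with ", config$mc_n, " MC draws")
  cum_rows <- list()
  for (key in names(series)) {
    s <- series[[key]]
    m <- s$monolith_id[1]
    v <- s$variable[1]
    for (wn in names(windows)) {
      w <- windows[[wn]]
      res <- tryCatch(cumulate_trapezoid(s, w), error = function(e) NULL)
      if (is.null(res)) {
        say("cumulate: ", m, "/", v, "/", wn, ": window not integrable")
        next
      }
      mc <- mc_cumulative_uncertainty(s, w, n = config$mc_n,
                                      seed = config$seed + match(key, names(series)))
      total <- res$total
      if (v == "sr") total <- total * 3600 / 1e6 # umol m-2 s-1 x h -> mol m-2
      cum_rows[[length(cum_rows) + 1]] <- data.frame(
        monolith_id = m, variable = v, window = wn,
        window_start = res$window_start, window_end = res$window_end,
        total = total,
        mc_sd = if (v == "sr") mc$mc_sd * 3600 / 1e6 else mc$mc_sd,
        mc_lo = if (v == "sr") mc$mc_lo * 3600 / 1e6 else mc$mc_lo,
        mc_hi = if (v == "sr") mc$mc_hi * 3600 / 1e6 else mc$mc_hi,
        fill_fraction = res$fill_fraction,
        stringsAsFactors = FALSE)
    }
  }
  cumulatives <- do.call(rbind, cum_rows)
  if (is.null(cumulatives)) {
    say("cumulate: no integrable window in any series")
    return(structure(list(
      measurements = meas, fluxes = fluxes, chi_na = fx$chi_na,
      series = series, cumulatives = NULL, summary = NULL, anova = NULL,
      exclusions = as.list(exclusions), log = log_lines,
      config = config, origin = origin, windows = windows
    ), class = "isopulse_run"))
  }

  say("partition: tracer fractions relative to uptake")
  rel_rows <- cumulatives[cumulatives$variable == "abs13c", , drop = FALSE]
  if (nrow(rel_rows) > 0) {
    U <- meta$uptake_mg13C_m2[match(rel_rows$monolith_id, meta$monolith_id)]
    rel_rows$total <- relative_tracer(rel_rows$total, U)
    rel_rows$mc_sd <- rel_rows$mc_sd / U
    rel_rows$mc_lo <- rel_rows$mc_lo / U
    rel_rows$mc_hi <- rel_rows$mc_hi / U
    rel_rows$variable <- "rel13c"
    cumulatives <- rbind(cumulatives, rel_rows)
  }

  summary_tab <- summarize_groups(cumulatives, meta)

  say("stats: ANOVA of drought x land use")
  anova_rows <- list()
  two_by_two <- length(unique(meta$treatment)) == 2 &&
    length(unique(meta$land_use)) == 2
  if (two_by_two) {
    for (v in unique(cumulatives$variable)) {
      for (wn in unique(cumulatives$window)) {
        d <- cumulatives[cumulatives$variable == v & cumulatives$window == wn, ]
        d <- merge(d, meta[, c("monolith_id", "treatment", "land_use")],
                   by = "monolith_id")
        counts <- table(d$treatment, d$land_use)
        if (length(counts) != 4 || min(counts) < 2 ||
            length(unique(as.integer(counts))) != 1) next
        pa <- tryCatch(
          permutation_anova(d$total, d$treatment, d$land_use,
                            n_perm = config$n_perm, seed = config$seed,
                            term_names = c("drought", "land_use")),
          error = function(e) NULL)
        if (is.null(pa)) next
        pa$variable <- v
        pa$window <- wn
        anova_rows[[paste(v, wn)]] <- pa
      }
    }
  } else {
    say("stats: design not 2x2; ANOVA skipped")
  }
  anova_tab <- if (length(anova_rows) > 0) do.call(rbind, anova_rows) else NULL

  run <- structure(list(
    measurements = meas, fluxes = fluxes, chi_na = fx$chi_na,
    series = series, cumulatives = cumulatives, summary = summary_tab,
    anova = anova_tab,
    exclusions = as.list(exclusions),
    log = log_lines,
    config = config, origin = origin, windows = windows
  ), class = "isopulse_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fluxes, file.path(out_dir, "flux_table.csv"),
                     row.names = FALSE)
    ser <- do.call(rbind, series)
    utils::write.csv(ser, file.path(out_dir, "series.csv"), row.names = FALSE)
    utils::write.csv(cumulatives, file.path(out_dir, "cumulatives.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(anova_tab)) {
      jsonlite::write_json(anova_tab, file.path(out_dir, "anova.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  run
}

#' Human-readable summary of a pipeline run
#'
#' One table per window and variable with group means +/- SD across
#' replicates, drought percent change, and (when computed) F and exact
#' permutation p-values.
#'
#' @param run An `isopulse_run` from [run_pipeline()], or a directory it was
#'   written to.
#' @param file Optional path to also write the report text to.
#' @return Invisibly, the report lines.
#' @export
make_report <- function(run, file = NULL) {
  if (is.character(run)) {
    summary_tab <- utils::read.csv(file.path(run, "summary.csv"))
    anova_tab <- if (file.exists(file.path(run, "anova.json"))) {
      jsonlite::fromJSON(file.path(run, "anova.json"))
    } else NULL
  } else {
    summary_tab <- run$summary
    anova_tab <- run$anova
  }
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Cumulative flux summary (group mean +/- SD across replicates)")
  add(strrep("=", 62))
  for (v in unique(summary_tab$variable)) {
    for (w in unique(summary_tab$window)) {
      d <- summary_tab[summary_tab$variable == v & summary_tab$window == w, ]
      if (nrow(d) == 0) next
      unit <- switch(v, sr = "mol CO2 m-2", abs13c = "mg 13C m-2",
                     rel13c = "fraction of uptake", "")
      add("")
      add(v, " | ", w, " window  [", unit, "]")
      for (i in seq_len(nrow(d))) {
        pc <- if (is.finite(d$percent_change[i])) {
          sprintf("  (%+.1f%% vs control)", d$percent_change[i])
        } else ""
        add(sprintf("  %-10s %-9s %9.4g +/- %-9.3g n=%d%s",
                    d$land_use[i], d$treatment[i], d$mean[i], d$sd[i],
                    d$n[i], pc))
      }
      if (!is.null(anova_tab)) {
        a <- anova_tab[anova_tab$variable == v & anova_tab$window == w, ]
        for (i in seq_len(nrow(a))) {
          add(sprintf("    %-12s F = %8.3f  p_F = %.3f  p_exact = %.3f (%s, n_perm=%d)",
                      a$term[i], a$F[i], a$p_classical[i], a$p_exact[i],
                      a$method[i], a$n_perm[i]))
        }
      }
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.isopulse_run <- function(x, ...) {
  cat("isopulse pipeline run:", nrow(x$fluxes), "flux observations,",
      length(x$series), "gridded series,",
      if (is.null(x$cumulatives)) 0 else nrow(x$cumulatives),
      "cumulative totals\n")
  cat("QC:", paste(names(x$exclusions), unlist(x$exclusions),
                   sep = "=", collapse = ", "), "\n")
  invisible(x)
}
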