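# Synthetic-data generator: forward model of the drought/rewetting/labelling
# experiment producing raw multiplexed analyzer streams, metadata and
# calibration tables, together with a closed-form ground-truth record
# (true rates, windowed integrals, fractions, MRT) that the pipeline never
# sees but tests compare against.
#
# Ground-truth model per monolith:
#   SR(t)  = B * m(t) * (1 + a_d(t) * sin(diel)) * birch(t)
#     m(t)     drought multiplier (default 0.5) while the drought is active
#     birch(t) 1 + (P-1) * exp(-(t - t_rw)/tau_b) after rewetting of
#              drought monoliths (Birch rewetting pulse, default P = 3,
#              tau_b = 12 h, i.e. decayed within ~2 days)
#     a_d(t)   diel amplitude, damped under active drought
#   r13(t) = U * R * [w_f k_f e^(-k_f tau) + w_s k_s e^(-k_s tau)]
#            * (1 + a13(t) * sin(diel))            for tau = t - t0 - delta >= 0
#            + U * w_rw k_rw e^(-k_rw (t - t_rw))  (drought, after rewetting)
#     two-pool tracer kinetics with delay delta (tracer appears ~1.5 h after
#     the start of the 75-min label pulse); R is the total fraction of
#     assimilated tracer respired belowground.
#
# Outlet concentrations are reconstructed by inverting the chamber flux and
# mixing equations, analyzer noise is added (defaults 0.200 / 0.010 umol/mol
# for 12CO2 / 13CO2), and the inverse of the configured span-offset
# distortion is applied so that the pipeline must undo it.

#' Define a synthetic labelling scenario
#'
#' Defaults encode the study conditions the generator emulates: ~50% drought
#' suppression of soil respiration, a 75-min label pulse, tracer efflux
#' appearing 1.5 h after label start and declining over days with diel
#' modulation (damped under drought), a rewetting pulse up to 3x control
#' decaying within ~2 days, analyzer noise of 200/10 ppb, 170 ml/min chamber
#' flow, ~2-h calibration cadence.
#'
#' @param land_uses,baseline Land-use levels and their baseline respiration
#'   B (umol m-2 s-1).
#' @param treatments,n_rep Treatment levels and replicates per cell.
#' @param campaign Campaign label stamped into the metadata.
#' @param baseline_cv Lognormal between-monolith jitter of B.
#' @param diel_amplitude,diel_peak_hour Diel modulation of SR.
#' @param drought_multiplier Multiplier m_d on SR while drought is active.
#' @param drought_diel_damping Factor applied to diel amplitudes under
#'   active drought.
#' @param birch_peak,birch_tau_h Rewetting (Birch) pulse peak factor P and
#'   decay constant (h).
#' @param tracer_delay_h Delay between label start and tracer appearance (h).
#' @param frac_respired Total fraction R of assimilated tracer respired
#'   belowground.
#' @param w_fast,k_fast,k_slow Two-pool tracer kinetics (weights w_fast and
#'   1 - w_fast; rates 1/h).
#' @param tracer_diel_amplitude Diel modulation of the tracer efflux.
#' @param rewet_remobilized,k_rewet Extra tracer fraction remobilized at
#'   rewetting (drought monoliths) and its decay rate (1/h).
#' @param uptake,uptake_cv Assimilated tracer U (mg 13C m-2) and its jitter.
#' @param chi_na Natural-abundance atom fraction of soil respiration.
#' @param co2_in Buffer (inlet) CO2 concentration (umol/mol).
#' @param noise_c12,noise_c13 Analyzer noise sds (umol/mol).
#' @param flow,flow_jitter Chamber flow mean and within-cycle jitter (ml/min).
#' @param cal_span,cal_offset Instrument distortion per isotopologue: the
#'   stream is emitted as measured = (true - offset)/span.
#' @param cal_gas_total,cal_gas_af Calibration-gas total CO2 levels
#'   (umol/mol) and their (known) 13C atom fraction.
#' @param cal_dwell_s Seconds each calibration gas is measured.
#' @param area Chamber footprint (m2).
#' @param origin POSIXct time of t = 0 (midnight, for the diel phase).
#' @param label_start_h,label_dur_min Label pulse start (h since origin) and
#'   duration (min).
#' @param chase_h Chase window after label end (h).
#' @param rewet_after_label_h Rewetting time relative to label start (h).
#' @param post_rewet_h Post-rewetting window (h).
#' @param sample_dt Analyzer sample spacing (s).
#' @param protocol A [measurement_protocol()].
#' @param seed Single RNG seed from which all randomness flows.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(land_uses = c("managed", "abandoned"),
                               baseline = c(managed = 3.5, abandoned = 2.5),
                               treatments = c("control", "drought"),
                               n_rep = 3,
                               campaign = "peak_drought",
                               baseline_cv = 0.05,
                               diel_amplitude = 0.3, diel_peak_hour = 14,
                               drought_multiplier = 0.5,
                               drought_diel_damping = 0.05,
                               birch_peak = 3, birch_tau_h = 12,
                               tracer_delay_h = 1.5,
                               frac_respired = 0.15,
                               w_fast = 0.7, k_fast = 1 / 12, k_slow = 1 / 96,
                               tracer_diel_amplitude = 0.3,
                               rewet_remobilized = 0.05, k_rewet = 1 / 12,
                               uptake = 500, uptake_cv = 0.1,
                               chi_na = 0.0108,
                               co2_in = 420,
                               noise_c12 = 0.200, noise_c13 = 0.010,
                               flow = 170, flow_jitter = 2,
                               cal_span = c(c12 = 0.98, c13 = 0.97),
                               cal_offset = c(c12 = 5, c13 = 0.2),
                               cal_gas_total = c(400, 1500, 5000),
                               cal_gas_af = 0.0108,
                               cal_dwell_s = 60,
                               area = pi * 0.0225^2,
                               origin = as.POSIXct("2014-06-20 00:00:00",
                                                   tz = "UTC"),
                               label_start_h = 34, label_dur_min = 75,
                               chase_h = 120,
                               rewet_after_label_h = 126, post_rewet_h = 72,
                               sample_dt = 2,
                               protocol = measurement_protocol(),
                               seed = 1) {
  sc <- as.list(environment())
  stopifnot(drought_multiplier > 0, drought_multiplier <= 1,
            birch_peak >= 1, k_fast > k_slow, k_slow > 0,
            noise_c12 >= 0, noise_c13 >= 0,
            w_fast >= 0, w_fast <= 1,
            frac_respired + rewet_remobilized <= 1)
  class(sc) <- "synthetic_scenario"
  sc
}

# diel factor: sinusoid peaking at `peak_hour` local time (origin = midnight)
.diel <- function(t_h, amplitude, peak_hour) {
  1 + amplitude * sin(2 * pi * (t_h - (peak_hour - 6)) / 24)
}

# closed-form true rate functions for one monolith
.truth_funs <- function(sc, drought, B, U) {
  t_rw <- sc$label_start_h + sc$rewet_after_label_h
  onset <- sc$label_start_h + sc$tracer_delay_h
  sr <- function(t_h) {
    active <- drought & t_h < t_rw
    m <- ifelse(active, sc$drought_multiplier, 1)
    a <- sc$diel_amplitude * ifelse(active, sc$drought_diel_damping, 1)
    birch <- ifelse(drought & t_h >= t_rw,
                    1 + (sc$birch_peak - 1) * exp(-(t_h - t_rw) / sc$birch_tau_h),
                    1)
    B * m * .diel(t_h, a, sc$diel_peak_hour) * birch
  }
  r13 <- function(t_h) {
    tau <- t_h - onset
    active <- drought & t_h < t_rw
    a13 <- sc$tracer_diel_amplitude * ifelse(active, sc$drought_diel_damping, 1)
    kern <- ifelse(tau >= 0,
                   sc$w_fast * sc$k_fast * exp(-sc$k_fast * pmax(tau, 0)) +
                     (1 - sc$w_fast) * sc$k_slow * exp(-sc$k_slow * pmax(tau, 0)),
                   0)
    main <- U * sc$frac_respired * kern * .diel(t_h, a13, sc$diel_peak_hour)
    rw <- ifelse(drought & t_h >= t_rw,
                 U * sc$rewet_remobilized * sc$k_rewet *
                   exp(-sc$k_rewet * pmax(t_h - t_rw, 0)),
                 0)
    main + rw
  }
  list(sr = sr, r13 = r13, onset = onset, t_rw = t_rw)
}

# adaptive quadrature split at known kinks
.truth_integral <- function(f, lo, hi, breaks) {
  pts <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total + stats::integrate(f, pts[i], pts[i + 1],
                                      rel.tol = 1e-10,
                                      subdivisions = 2000L)$value
  }
  total
}

#' Generate a full synthetic scenario
#'
#' Produces the raw multiplexed analyzer stream (with analyzer noise and
#' inverse calibration distortion applied), the flow log, monolith metadata,
#' calibration-gas definitions, and the ground-truth record. All randomness
#' flows from the scenario seed.
#'
#' @param sc A [synthetic_scenario()].
#' @return list(`records` (analyzer_stream), `flow`, `meta`, `cal_gases`,
#'   `truth`, `scenario`). `truth` holds per-monolith closed-form rate
#'   functions (`sr_fun`, `r13_fun`), the analytic windowed integrals
#'   (`per_monolith`), and the evaluation windows (`windows`, hours).
#' @export
generate_scenario <- function(sc = synthetic_scenario()) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  .with_seed(sc$seed, {
    design <- expand.grid(rep = seq_len(sc$n_rep),
                          treatment = sc$treatments,
                          land_use = sc$land_uses,
                          stringsAsFactors = FALSE)
    n_mono <- nrow(design)
    ids <- sprintf("M%02d", seq_len(n_mono))
    B <- unname(sc$baseline[design$land_use]) *
      exp(stats::rnorm(n_mono, 0, sc$baseline_cv) - sc$baseline_cv^2 / 2)
    U <- sc$uptake *
      exp(stats::rnorm(n_mono, 0, sc$uptake_cv) - sc$uptake_cv^2 / 2)
    label_start <- sc$origin + sc$label_start_h * 3600
    label_end <- label_start + sc$label_dur_min * 60
    t_rw_h <- sc$label_start_h + sc$rewet_after_label_h
    rewetting <- sc$origin + t_rw_h * 3600
    meta <- data.frame(
      monolith_id = ids,
      land_use = design$land_use,
      treatment = design$treatment,
      campaign = sc$campaign,
      block = design$rep,
      area_m2 = sc$area,
      uptake_mg13C_m2 = U,
      label_start = label_start,
      label_end = label_end,
      rewetting_time = rewetting,
      stringsAsFactors = FALSE
    )
    funs <- lapply(seq_len(n_mono), function(i) {
      .truth_funs(sc, design$treatment[i] == "drought", B[i], U[i])
    })
    names(funs) <- ids

    # ---- truth: analytic windowed integrals -------------------------------
    label_end_h <- sc$label_start_h + sc$label_dur_min / 60
    windows <- list(chase = c(label_end_h, label_end_h + sc$chase_h),
                    rewet = c(t_rw_h, t_rw_h + sc$post_rewet_h))
    per_mono <- do.call(rbind, lapply(seq_len(n_mono), function(i) {
      f <- funs[[i]]
      brk <- c(f$onset, f$t_rw)
      sr_chase <- .truth_integral(f$sr, windows$chase[1], windows$chase[2], brk)
      sr_rewet <- .truth_integral(f$sr, windows$rewet[1], windows$rewet[2], brk)
      r13_chase <- .truth_integral(f$r13, windows$chase[1], windows$chase[2], brk)
      r13_rewet <- .truth_integral(f$r13, windows$rewet[1], windows$rewet[2], brk)
      data.frame(monolith_id = ids[i], B = B[i], U = U[i], chi_na = sc$chi_na,
                 sr_chase_mol = sr_chase * 3600 / 1e6,
                 r13_chase_mg = r13_chase,
                 rel13c_chase = r13_chase / U[i],
                 sr_rewet_mol = sr_rewet * 3600 / 1e6,
                 r13_rewet_mg = r13_rewet,
                 rel13c_rewet = r13_rewet / U[i],
                 stringsAsFactors = FALSE)
    }))

    # ---- raw stream -------------------------------------------------------
    proto <- sc$protocol
    cycle_s <- proto$inlet_pre + proto$outlet + proto$inlet_post
    cal_s <- 3 * sc$cal_dwell_s
    sweep_s <- n_mono * cycle_s + cal_s
    duration_s <- (t_rw_h + sc$post_rewet_h + 2) * 3600
    n_sweep <- floor(duration_s / sweep_s)
    if (n_sweep < 2) stop("generate_scenario: scenario too short for two sweeps")
    cal_gases <- data.frame(
      gas_id = paste0("G", seq_along(sc$cal_gas_total)),
      total_co2_ppm = sc$cal_gas_total,
      atom_fraction_13C = sc$cal_gas_af
    )
    c13_in_true <- sc$chi_na * sc$co2_in
    c12_in_true <- (1 - sc$chi_na) * sc$co2_in
    r13_to_molar <- 1000 / (.M13 * 3600) # mg m-2 hr-1 -> umol m-2 s-1

    chunks <- vector("list", n_sweep * (n_mono + nrow(cal_gases)))
    flow_chunks <- vector("list", n_sweep * n_mono)
    ci <- 0
    fi <- 0
    distort <- function(true12, true13) {
      m12 <- (true12 + stats::rnorm(length(true12), 0, sc$noise_c12) -
                sc$cal_offset[["c12"]]) / sc$cal_span[["c12"]]
      m13 <- (true13 + stats::rnorm(length(true13), 0, sc$noise_c13) -
                sc$cal_offset[["c13"]]) / sc$cal_span[["c13"]]
      list(c12 = m12, c13 = m13)
    }
    for (s in seq_len(n_sweep)) {
      sweep_start <- (s - 1) * sweep_s
      for (i in seq_len(n_mono)) {
        cyc0 <- sweep_start + (i - 1) * cycle_s
        off <- seq(0, cycle_s - sc$sample_dt, by = sc$sample_dt)
        tt <- cyc0 + off
        seg <- findInterval(off, c(proto$inlet_pre,
                                   proto$inlet_pre + proto$outlet)) # 0,1,2
        n_samp <- length(off)
        t_h <- tt / 3600
        # flow log for the outlet window
        out_sel <- seg == 1
        f_samp <- sc$flow + stats::rnorm(sum(out_sel), 0, sc$flow_jitter)
        f_mean <- mean(f_samp)
        fm <- .molar_flow(f_mean)
        sr_t <- funs[[i]]$sr(t_h)
        r13m <- funs[[i]]$r13(t_h) * r13_to_molar
        chi_src <- sc$chi_na + r13m / sr_t
        if (any(chi_src < 0 | chi_src > 1)) {
          stop("generate_scenario: implied source atom fraction outside [0,1] ",
               "(monolith ", ids[i], ", 13C efflux exceeds total C efflux); ",
               "scenario rejected")
        }
        d_co2 <- sr_t * sc$area / fm
        co2_out <- sc$co2_in + d_co2
        chi_out <- (sc$chi_na * sc$co2_in + chi_src * d_co2) / co2_out
        if (any(chi_out < 0 | chi_out > 1)) {
          stop("generate_scenario: implied outlet atom fraction outside [0,1] ",
               "(monolith ", ids[i], "); scenario rejected")
        }
        c13_true <- ifelse(out_sel, chi_out * co2_out, c13_in_true)
        c12_true <- ifelse(out_sel, co2_out - chi_out * co2_out, c12_in_true)
        m <- distort(c12_true, c13_true)
        ci <- ci + 1
        chunks[[ci]] <- data.frame(
          t_s = tt,
          line_id = ifelse(out_sel, paste0("chamber-", ids[i]),
                           paste0("buffer-", ids[i])),
          c12 = m$c12, c13 = m$c13, stringsAsFactors = FALSE
        )
        fi <- fi + 1
        flow_chunks[[fi]] <- data.frame(t_s = tt[out_sel],
                                        flow_ml_min = f_samp)
      }
      # calibration cycle at the end of the sweep
      cal0 <- sweep_start + n_mono * cycle_s
      for (g in seq_len(nrow(cal_gases))) {
        off <- seq(0, sc$cal_dwell_s - sc$sample_dt, by = sc$sample_dt)
        tt <- cal0 + (g - 1) * sc$cal_dwell_s + off
        tot <- cal_gases$total_co2_ppm[g]
        af <- cal_gases$atom_fraction_13C[g]
        m <- distort(rep(tot * (1 - af), length(tt)), rep(tot * af, length(tt)))
        ci <- ci + 1
        chunks[[ci]] <- data.frame(
          t_s = tt, line_id = paste0("cal-", cal_gases$gas_id[g]),
          c12 = m$c12, c13 = m$c13, stringsAsFactors = FALSE
        )
      }
    }
    raw <- do.call(rbind, chunks[seq_len(ci)])
    rec <- data.frame(time = sc$origin + raw$t_s, line_id = raw$line_id,
                      c12 = raw$c12, c13 = raw$c13, stringsAsFactors = FALSE)
    records <- as_analyzer_stream(rec)
    fl <- do.call(rbind, flow_chunks[seq_len(fi)])
    flow <- data.frame(time = sc$origin + fl$t_s,
                       flow_ml_min = fl$flow_ml_min)

    truth <- list(
      per_monolith = per_mono,
      windows = windows,
      sr_fun = function(monolith_id, t_h) funs[[monolith_id]]$sr(t_h),
      r13_fun = function(monolith_id, t_h) funs[[monolith_id]]$r13(t_h),
      onset_h = sc$label_start_h + sc$tracer_delay_h,
      label_end_h = label_end_h,
      rewet_h = t_rw_h
    )
    list(records = records, flow = flow, meta = meta, cal_gases = cal_gases,
         truth = truth, scenario = sc)
  })
}

#' Generate a dark-pulse back-diffusion series
#'
#' Single-exponential tracer efflux with a prescribed mean residence time,
#' for testing the back-diffusion kinetics fit. The dark pulse excludes
#' photosynthetic uptake, so the observed efflux is pure physical
#' back-diffusion.
#'
#' @param mrt_min True mean residence time (min).
#' @param r0 Initial efflux (mg 13C m-2 hr-1).
#' @param noise_sd Additive Gaussian noise sd (same units as `r0`).
#' @param duration_min,dt_min Series length and spacing (min).
#' @param seed RNG seed.
#' @return list(`series` = data.frame(`time_min`, `efflux`),
#'   `truth` = list(`mrt_min`, `k`, `r0`)).
#' @export
generate_dark_pulse <- function(mrt_min = 23, r0 = 10, noise_sd = 0,
                                duration_min = 120, dt_min = 2, seed = 1) {
  stopifnot(mrt_min > 0)
  .with_seed(seed, {
    t <- seq(0, duration_min, by = dt_min)
    v <- r0 * exp(-t / mrt_min) + stats::rnorm(length(t), 0, noise_sd)
    list(series = data.frame(time_min = t, efflux = v),
         truth = list(mrt_min = mrt_min, k = 1 / mrt_min, r0 = r0))
  })
}

#' Generate synthetic leachate samples
#'
#' Assigns leachate volumes, DOC concentrations and 13C atom fractions per
#' monolith and sampling occasion, emulating lower leachate volumes but
#' elevated DOC and DO13C concentrations under drought after rewetting, plus
#' unlabelled reference monoliths carrying natural abundance. Hydrology is
#' not modelled; values are drawn around group means.
#'
#' @param meta Monolith metadata (labelled monoliths).
#' @param n_unlabelled Reference monoliths without label.
#' @param seed RNG seed.
#' @return A leachate sample table (see [read_leachates()]).
#' @export
generate_leachates <- function(meta, n_unlabelled = 4, seed = 1) {
  .with_seed(seed, {
    occasions <- c("pre_drought", "post_rewetting_0d", "post_rewetting_3d")
    ref_ids <- sprintf("R%02d", seq_len(n_unlabelled))
    all_ids <- c(meta$monolith_id, ref_ids)
    trt <- c(meta$treatment, rep("control", n_unlabelled))
    labelled <- c(rep(TRUE, nrow(meta)), rep(FALSE, n_unlabelled))
    rows <- list()
    for (occ in occasions) {
      for (j in seq_along(all_ids)) {
        drought <- trt[j] == "drought"
        vol <- switch(occ,
                      pre_drought = 1.5,
                      post_rewetting_0d = if (drought) 0.6 else 1.8,
                      post_rewetting_3d = if (drought) 0.4 else 1.0)
        vol <- max(0, vol * exp(stats::rnorm(1, 0, 0.15)))
        doc <- switch(occ,
                      pre_drought = 12,
                      post_rewetting_0d = if (drought) 30 else 14,
                      post_rewetting_3d = if (drought) 18 else 12)
        doc <- doc * exp(stats::rnorm(1, 0, 0.1))
        excess <- if (!labelled[j] || occ == "pre_drought") 0 else {
          base <- if (drought) 0.004 else 0.002
          if (occ == "post_rewetting_3d") base <- base / 2
          base
        }
        chi <- 0.0108 + excess + stats::rnorm(1, 0, 1e-4)
        rows[[length(rows) + 1]] <- data.frame(
          monolith_id = all_ids[j], sampling = occ,
          volume_L = vol, doc_mg_per_L = doc, doc_sd = 0.05 * doc,
          chi_c = chi, chi_c_sd = 1e-4, labelled = labelled[j],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
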