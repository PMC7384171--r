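# Raw analyzer stream I/O and segmentation into chamber measurement cycles.
#
# Line-id convention for the multiplexed stream:
#   "chamber-<monolith_id>"  chamber outlet of a monolith
#   "buffer-<monolith_id>"   buffer-volume inlet air of a monolith
#   "cal-<gas_id>"           calibration gas
#
# All delimited files are comma-separated, "." decimal, UTF-8, header row
# mandatory; timestamps are UTC at second resolution, windows are half-open
# [start, end).

#' Default measurement protocol
#'
#' One chamber measurement cycle is 100 s of inlet (buffer) air, 250 s of
#' chamber outlet air, and another 100 s of inlet air. The first `dead_band`
#' seconds of each window are discarded as line-switch transients.
#'
#' @param inlet_pre,outlet,inlet_post Window lengths (s).
#' @param dead_band Seconds discarded at the start of each window.
#' @return A named list.
#' @export
measurement_protocol <- function(inlet_pre = 100, outlet = 250,
                                 inlet_post = 100, dead_band = 30) {
  stopifnot(dead_band >= 0, dead_band < min(inlet_pre, outlet, inlet_post))
  list(inlet_pre = inlet_pre, outlet = outlet, inlet_post = inlet_post,
       dead_band = dead_band)
}

#' Read a raw analyzer stream
#'
#' Reads a long-format CSV of timestamped 12CO2/13CO2 isotopologue
#' concentrations on multiplexed gas lines, sorts records by time, flags
#' (without dropping) negative concentrations, and rejects duplicate
#' (time, line_id) records beyond the first.
#'
#' @param path CSV file with columns mappable to time, line_id, c12, c13.
#' @param schema Named character vector mapping canonical names
#'   (`time`, `line_id`, `c12`, `c13`) to file column names.
#' @param tz Timezone of the timestamps (default UTC).
#' @return A data.frame (class `analyzer_stream`) with columns `time`
#'   (POSIXct), `line_id`, `c12`, `c13` (umol/mol), `flag_negative`,
#'   `calibrated`; attributes `n_read`, `n_rejected`, `n_reordered`.
#' @export
read_analyzer_stream <- function(path,
                                 schema = c(time = "time", line_id = "line_id",
                                            c12 = "c12_ppm", c13 = "c13_ppm"),
                                 tz = "UTC") {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[c("time", "line_id", "c12", "c13")]),
                          names(raw))
  if (length(missing_cols) > 0) {
    stop("analyzer stream ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  tstr <- as.character(raw[[schema[["time"]]]])
  time <- as.POSIXct(tstr, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  retry <- is.na(time)
  if (any(retry)) { # tolerate the ISO-8601 'T' separator
    time[retry] <- as.POSIXct(tstr[retry], tz = tz,
                              format = "%Y-%m-%dT%H:%M:%S")
  }
  bad <- which(is.na(time) | is.na(tstr))
  if (length(bad) > 0) {
    stop("analyzer stream ", path, ": unparseable timestamp at data row ",
         bad[1], " (value '", raw[[schema[["time"]]]][bad[1]], "')")
  }
  rec <- data.frame(
    time = time,
    line_id = as.character(raw[[schema[["line_id"]]]]),
    c12 = as.numeric(raw[[schema[["c12"]]]]),
    c13 = as.numeric(raw[[schema[["c13"]]]]),
    stringsAsFactors = FALSE
  )
  as_analyzer_stream(rec)
}

#' Build an analyzer stream from in-memory records
#'
#' Applies the same ordering, duplicate-rejection and negative-value flagging
#' contract as [read_analyzer_stream()].
#'
#' @param rec data.frame with columns `time`, `line_id`, `c12`, `c13`.
#' @return An `analyzer_stream` data.frame.
#' @export
as_analyzer_stream <- function(rec) {
  stopifnot(all(c("time", "line_id", "c12", "c13") %in% names(rec)))
  n_read <- nrow(rec)
  ord <- order(rec$time)
  n_reordered <- sum(ord != seq_len(n_read))
  if (n_reordered > 0) {
    message("analyzer stream: ", n_reordered, " record(s) out of order; sorted")
  }
  rec <- rec[ord, , drop = FALSE]
  dup <- duplicated(rec[, c("time", "line_id")])
  n_rejected <- sum(dup)
  if (n_rejected > 0) {
    message("analyzer stream: rejected ", n_rejected,
            " duplicate (time, line_id) record(s)")
    rec <- rec[!dup, , drop = FALSE]
  }
  rec$flag_negative <- rec$c12 < 0 | rec$c13 < 0
  if (is.null(rec$calibrated)) rec$calibrated <- FALSE
  rownames(rec) <- NULL
  structure(rec,
            n_read = n_read, n_rejected = n_rejected,
            n_reordered = n_reordered,
            class = c("analyzer_stream", "data.frame"))
}

#' Write an analyzer stream CSV
#'
#' Inverse of [read_analyzer_stream()]: emits the canonical
#' `time,line_id,c12_ppm,c13_ppm` schema.
#'
#' @param records An `analyzer_stream` data.frame.
#' @param path Output path.
#' @export
write_analyzer_stream <- function(records, path) {
  out <- data.frame(
    time = format(records$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    line_id = records$line_id,
    c12_ppm = records$c12,
    c13_ppm = records$c13
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read monolith metadata
#'
#' Schema: `monolith_id,land_use,treatment,campaign,block,area_m2,
#' uptake_mg13C_m2,label_start,label_end,rewetting_time`. Land use is
#' managed/abandoned, treatment control/drought, campaign
#' peak_drought/recovery. `uptake_mg13C_m2` is the total assimilated tracer U
#' (shoots + roots, determined externally); it is an input, never computed
#' here.
#'
#' @param path CSV path.
#' @param tz Timezone for the timestamp columns.
#' @return data.frame of monolith metadata.
#' @export
read_monolith_meta <- function(path, tz = "UTC") {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("monolith_id", "land_use", "treatment", "campaign", "block",
              "area_m2", "uptake_mg13C_m2", "label_start", "label_end",
              "rewetting_time")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    stop("monolith metadata: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("label_start", "label_end", "rewetting_time")) {
    meta[[col]] <- as.POSIXct(meta[[col]], tz = tz)
  }
  if (any(meta$area_m2 <= 0)) stop("monolith metadata: area_m2 must be > 0")
  labelled <- is.finite(meta$uptake_mg13C_m2) & meta$uptake_mg13C_m2 > 0
  if (any(!labelled & !is.na(meta$uptake_mg13C_m2) & meta$uptake_mg13C_m2 != 0)) {
    stop("monolith metadata: uptake_mg13C_m2 must be > 0 for labelled monoliths")
  }
  meta
}

# decompose a line id into kind ("chamber", "buffer", "cal") and target id
.line_kind <- function(line_id) sub("-.*$", "", line_id)
.line_target <- function(line_id) sub("^[^-]+-", "", line_id)

# mean/sd/n summary of one window after dead-band removal; half-open [start, end)
.window_summary <- function(times, values, start, end, dead_band) {
  keep <- times >= (start + dead_band) & times < end
  v <- values[keep]
  if (length(v) == 0) {
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
}

#' Summarize one chamber measurement cycle
#'
#' Takes the analyzer records of a single inlet/outlet/inlet cycle
#' (pre-inlet buffer window, chamber outlet window, post-inlet buffer window,
#' identified by their line ids) and summarizes each isotopologue to
#' mean/sd/n per window after discarding the first `dead_band` seconds of
#' each window. The two inlet windows are pooled with equal weight.
#'
#' @param records `analyzer_stream` rows covering exactly one cycle.
#' @param protocol A [measurement_protocol()].
#' @param flow Optional data.frame `time,flow_ml_min` of logged flow; summarized
#'   over the cycle window. If `NULL`, `flow_mean`/`flow_sd` are `NA`.
#' @return One-row data.frame (a ChamberMeasurement): `monolith_id`, `t_mid`,
#'   `inlet12_mean/sd/n`, `inlet13_*`, `outlet12_*`, `outlet13_*`,
#'   `flow_mean`, `flow_sd`, `window_start`, `window_end`, `valid`.
#' @export
segment_measurement <- function(records, protocol = measurement_protocol(),
                                flow = NULL) {
  kind <- .line_kind(records$line_id)
  runs <- rle(records$line_id)
  if (length(runs$values) != 3 ||
      !identical(.line_kind(runs$values), c("buffer", "chamber", "buffer"))) {
    stop("segment_measurement: expected buffer/chamber/buffer runs, got ",
         paste(runs$values, collapse = ","))
  }
  monolith <- .line_target(runs$values[2])
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1, utils::head(idx_end, -1) + 1)
  tt <- as.numeric(records$time)
  # window bounds: run start to start of next run (half-open); last run closes
  # one nominal sample spacing after its final record
  dt <- stats::median(diff(tt))
  bounds <- c(tt[idx_start], tt[idx_end[3]] + dt)
  db <- protocol$dead_band
  w <- vector("list", 3)
  for (i in 1:3) {
    sel <- idx_start[i]:idx_end[i]
    w[[i]] <- list(
      c12 = .window_summary(tt[sel], records$c12[sel], bounds[i], bounds[i + 1], db),
      c13 = .window_summary(tt[sel], records$c13[sel], bounds[i], bounds[i + 1], db)
    )
  }
  valid <- all(vapply(w, function(x) x$c12$n > 0 && x$c13$n > 0, logical(1)))
  pool <- function(a, b) {
    # equal-weight pooling of the pre and post inlet windows
    if (a$n == 0 || b$n == 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
    m <- (a$mean + b$mean) / 2
    # pooled spread: within-window variance plus between-window separation
    v <- (a$sd^2 + b$sd^2) / 2 + (a$mean - b$mean)^2 / 4
    list(mean = m, sd = sqrt(v), n = a$n + b$n)
  }
  in12 <- pool(w[[1]]$c12, w[[3]]$c12)
  in13 <- pool(w[[1]]$c13, w[[3]]$c13)
  fl <- list(mean = NA_real_, sd = NA_real_)
  if (!is.null(flow)) {
    ft <- as.numeric(flow$time)
    keep <- ft >= bounds[2] & ft < bounds[3]
    if (any(keep)) {
      fv <- flow$flow_ml_min[keep]
      fl <- list(mean = mean(fv), sd = if (length(fv) > 1) stats::sd(fv) else 0)
    }
  }
  data.frame(
    monolith_id = monolith,
    t_mid = records$time[1] + (bounds[2] + bounds[3]) / 2 - tt[1],
    inlet12_mean = in12$mean, inlet12_sd = in12$sd, inlet12_n = in12$n,
    inlet13_mean = in13$mean, inlet13_sd = in13$sd, inlet13_n = in13$n,
    outlet12_mean = w[[2]]$c12$mean, outlet12_sd = w[[2]]$c12$sd,
    outlet12_n = w[[2]]$c12$n,
    outlet13_mean = w[[2]]$c13$mean, outlet13_sd = w[[2]]$c13$sd,
    outlet13_n = w[[2]]$c13$n,
    flow_mean = fl$mean, flow_sd = fl$sd,
    window_start = records$time[1],
    window_end = records$time[1] + (bounds[4] - bounds[1]),
    valid = valid,
    stringsAsFactors = FALSE
  )
}

#' Segment a full multiplexed stream into chamber measurements
#'
#' Scans the stream for chamber-outlet runs framed by buffer-inlet runs of the
#' same monolith and summarizes each such cycle with [segment_measurement()].
#' Calibration-gas runs are ignored here (see [segment_calibration()]).
#'
#' @inheritParams segment_measurement
#' @param records Full `analyzer_stream`.
#' @return data.frame of ChamberMeasurement rows.
#' @export
segment_stream <- function(records, protocol = measurement_protocol(),
                           flow = NULL) {
  runs <- rle(records$line_id)
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1, utils::head(idx_end, -1) + 1)
  kinds <- .line_kind(runs$values)
  out <- list()
  for (j in seq_along(runs$values)) {
    if (kinds[j] != "chamber") next
    if (j == 1 || j == length(runs$values)) next
    mono <- .line_target(runs$values[j])
    ok <- identical(runs$values[j - 1], paste0("buffer-", mono)) &&
      identical(runs$values[j + 1], paste0("buffer-", mono))
    if (!ok) next
    sel <- idx_start[j - 1]:idx_end[j + 1]
    out[[length(out) + 1]] <-
      segment_measurement(records[sel, , drop = FALSE], protocol, flow)
  }
  if (length(out) == 0) {
    stop("segment_stream: no complete chamber measurement cycles found")
  }
  do.call(rbind, out)
}

#' Summarize calibration-gas runs
#'
#' Finds runs on `cal-<gas_id>` lines, summarizes each after dead-band
#' removal, and groups consecutive gas runs into calibration cycles.
#'
#' @param records Full `analyzer_stream`.
#' @param dead_band Seconds discarded at the start of each gas run.
#' @return data.frame: `cycle`, `gas_id`, `time` (run midpoint),
#'   `c12_mean`, `c12_sd`, `c13_mean`, `c13_sd`, `n`.
#' @export
segment_calibration <- function(records, dead_band = 30) {
  runs <- rle(records$line_id)
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1, utils::head(idx_end, -1) + 1)
  is_cal <- .line_kind(runs$values) == "cal"
  if (!any(is_cal)) return(NULL)
  # consecutive cal runs (possibly separated only by other cal runs) form a cycle
  cyc <- cumsum(is_cal & !c(FALSE, utils::head(is_cal, -1)))
  out <- list()
  for (j in which(is_cal)) {
    sel <- idx_start[j]:idx_end[j]
    tt <- as.numeric(records$time[sel])
    dt <- if (length(tt) > 1) stats::median(diff(tt)) else 1
    s12 <- .window_summary(tt, records$c12[sel], tt[1], tt[length(tt)] + dt, dead_band)
    s13 <- .window_summary(tt, records$c13[sel], tt[1], tt[length(tt)] + dt, dead_band)
    out[[length(out) + 1]] <- data.frame(
      cycle = cyc[j],
      gas_id = .line_target(runs$values[j]),
      time = mean(records$time[sel]),
      c12_mean = s12$mean, c12_sd = s12$sd,
      c13_mean = s13$mean, c13_sd = s13$sd,
      n = s12$n, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Print the delimited-text schemas understood by the package
#'
#' @return Invisibly, a named list of schema strings.
#' @export
isopulse_schemas <- function() {
  schemas <- list(
    analyzer_stream = "time,line_id,c12_ppm,c13_ppm",
    monolith_meta = paste0("monolith_id,land_use,treatment,campaign,block,",
                           "area_m2,uptake_mg13C_m2,label_start,label_end,",
                           "rewetting_time"),
    calibration_gases = "gas_id,total_co2_ppm,atom_fraction_13C",
    flux_table = paste0("monolith_id,t_mid,sr,sr_sd,chi_sr,chi_sr_sd,",
                        "chi_excess,chi_excess_sd,abs13c,abs13c_sd,qc"),
    series = "monolith_id,variable,time,value,sd,mask",
    cumulative = paste0("monolith_id,variable,window_start,window_end,total,",
                        "mc_sd,mc_lo,mc_hi,fill_fraction"),
    leachates = "monolith_id,sampling,volume_L,doc_mg_per_L,doc_sd,chi_c,chi_c_sd,labelled"
  )
  for (nm in names(schemas)) cat(nm, ": ", schemas[[nm]], "\n", sep = "")
  invisible(schemas)
}
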