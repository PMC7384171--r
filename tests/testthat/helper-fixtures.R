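# Shared fixture builders. Everything is generated in code; no data files.

.origin <- as.POSIXct("2014-06-20 00:00:00", tz = "UTC")

# a minimal well-formed analyzer record table
make_records <- function(times_s, line_id, c12, c13, origin = .origin) {
  data.frame(time = origin + times_s, line_id = line_id,
             c12 = c12, c13 = c13, stringsAsFactors = FALSE)
}

# one full 100/250/100-s cycle for monolith `id` at 1-s cadence with
# constant (or supplied) concentrations
make_cycle <- function(id = "M01", start_s = 0,
                       inlet12 = 400, inlet13 = 4.4,
                       outlet12 = NULL, outlet13 = NULL, origin = .origin) {
  off <- 0:449
  seg <- findInterval(off, c(100, 350))
  line <- ifelse(seg == 1, paste0("chamber-", id), paste0("buffer-", id))
  rep_len <- function(x, default) {
    if (is.null(x)) default else x
  }
  c12 <- ifelse(seg == 1, rep_len(outlet12, inlet12), inlet12)
  c13 <- ifelse(seg == 1, rep_len(outlet13, inlet13), inlet13)
  make_records(start_s + off, line, c12, c13, origin)
}

# small noise-free scenario shared by closure-style tests; overrides win
closure_scenario <- function(...) {
  args <- list(
    land_uses = "managed", baseline = c(managed = 3),
    treatments = "control", n_rep = 1,
    baseline_cv = 0, uptake_cv = 0,
    noise_c12 = 0, noise_c13 = 0, flow_jitter = 0,
    diel_amplitude = 0, tracer_diel_amplitude = 0,
    label_start_h = 12, chase_h = 120,
    rewet_after_label_h = 126, post_rewet_h = 4,
    seed = 1)
  args[names(list(...))] <- list(...)
  do.call(synthetic_scenario, args)
}

# a balanced 2x2 design with n replicates per cell
design_2x2 <- function(n = 3) {
  list(a = rep(c("control", "drought"), each = 2 * n),
       b = rep(rep(c("managed", "abandoned"), each = n), 2))
}
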