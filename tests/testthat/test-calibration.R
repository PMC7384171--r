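# Span-offset calibration: fitting, time-interpolated application, guards.

test_that("fitting measured = true gives the identity line", {
  true <- c(400, 1500, 5000) * (1 - 0.0108)
  cv <- fit_span_offset(true, true, "c12")
  expect_equal(cv$span, 1, tolerance = 1e-12)
  expect_equal(cv$offset, 0, tolerance = 1e-9)
  expect_equal(cv$residual_sd, 0, tolerance = 1e-9)
})

test_that("a known affine distortion is recovered exactly", {
  true <- c(400, 1500, 5000)
  measured <- (true - 5) / 0.98 # generator: true = 0.98 * measured + 5
  cv <- fit_span_offset(measured, true, "c12")
  expect_equal(cv$span, 0.98, tolerance = 1e-12)
  expect_equal(cv$offset, 5, tolerance = 1e-9)
})

test_that("two gases give exact interpolation with zero residual", {
  cv <- fit_span_offset(c(4, 50), c(4.1, 50.3), "c13")
  expect_equal(cv$residual_sd, 0)
  expect_equal(cv$n, 2)
})

test_that("identical measured values at different true values are singular", {
  expect_error(fit_span_offset(c(400, 400, 400), c(400, 1500, 5000), "c12"),
               "singular")
})

test_that("identity curves leave records unchanged; affine curves apply directly", {
  rec <- as_analyzer_stream(make_records(0:9, "buffer-M01", 1000, 10))
  t0 <- rec$time[1]
  identity_curves <- rbind(
    data.frame(isotopologue = "c12", span = 1, offset = 0, fit_time = t0,
               range_lo = 400, range_hi = 5000, residual_sd = 0, n = 3),
    data.frame(isotopologue = "c13", span = 1, offset = 0, fit_time = t0,
               range_lo = 4, range_hi = 50, residual_sd = 0, n = 3))
  got <- apply_calibration(rec, identity_curves)
  expect_equal(got$c12, rec$c12)
  expect_true(all(got$calibrated))

  affine <- identity_curves
  affine$span <- c(0.98, 0.98)
  affine$offset <- c(5, 0.2)
  got2 <- apply_calibration(rec, affine)
  expect_equal(got2$c12, 0.98 * rec$c12 + 5)
  expect_equal(got2$c13, 0.98 * rec$c13 + 0.2)
})

test_that("span interpolates linearly in time between bracketing fits", {
  t0 <- .origin
  rec <- as_analyzer_stream(make_records(3600, "buffer-M01", 1000, 10))
  curves <- rbind(
    data.frame(isotopologue = "c12", span = 1.00, offset = 0, fit_time = t0,
               range_lo = 400, range_hi = 5000, residual_sd = 0, n = 3),
    data.frame(isotopologue = "c12", span = 1.02, offset = 0,
               fit_time = t0 + 7200,
               range_lo = 400, range_hi = 5000, residual_sd = 0, n = 3),
    data.frame(isotopologue = "c13", span = 1, offset = 0, fit_time = t0,
               range_lo = 4, range_hi = 50, residual_sd = 0, n = 3))
  got <- apply_calibration(rec, curves)
  # record at t = 1 h between fits at 0 h and 2 h: span = 1.01
  expect_equal(got$c12, 1010, tolerance = 1e-12)
})

test_that("stale records are flagged and double application is an error", {
  t0 <- .origin
  rec <- as_analyzer_stream(make_records(c(0, 8 * 3600), "buffer-M01", 1000, 10))
  curves <- rbind(
    data.frame(isotopologue = "c12", span = 1, offset = 0, fit_time = t0,
               range_lo = 400, range_hi = 5000, residual_sd = 0, n = 3),
    data.frame(isotopologue = "c13", span = 1, offset = 0, fit_time = t0,
               range_lo = 4, range_hi = 50, residual_sd = 0, n = 3))
  got <- apply_calibration(rec, curves, staleness_hours = 6)
  expect_equal(got$flag_uncalibrated, c(FALSE, TRUE))
  expect_error(apply_calibration(got, curves), "already calibrated")
})

test_that("distort-fit-apply round-trips synthetic truth", {
  # distort a noise-free stream by a known (span, offset), fit curves from
  # distorted calibration-gas readings, apply, and recover the truth
  span <- c(c12 = 0.97, c13 = 0.95)
  offset <- c(c12 = 4, c13 = 0.15)
  gases <- data.frame(gas_id = c("G1", "G2", "G3"),
                      total_co2_ppm = c(400, 1500, 5000),
                      atom_fraction_13C = 0.0108)
  gt <- calibration_gas_truth(gases)
  cal_seg <- data.frame(
    cycle = 1, gas_id = gases$gas_id, time = .origin + 0:2,
    c12_mean = (gt$true_c12 - offset["c12"]) / span["c12"],
    c12_sd = 0,
    c13_mean = (gt$true_c13 - offset["c13"]) / span["c13"],
    c13_sd = 0, n = 30)
  curves <- fit_calibration_cycles(cal_seg, gases)
  true12 <- c(450, 800, 1200)
  true13 <- c(5, 9, 13)
  rec <- as_analyzer_stream(make_records(
    0:2, "buffer-M01",
    (true12 - offset["c12"]) / span["c12"],
    (true13 - offset["c13"]) / span["c13"]))
  got <- apply_calibration(rec, curves)
  expect_equal(got$c12, true12, tolerance = 1e-9)
  expect_equal(got$c13, true13, tolerance = 1e-9)
})
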