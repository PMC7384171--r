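# Spline alignment, gap masking, trapezoid cumulation, MC uncertainty.

test_that("splines reproduce a line for any penalty and a cubic at zero penalty", {
  t <- seq(0, 48, by = 0.5)
  y_line <- 2 * t + 1
  for (spar in c(0.05, 0.5, 1)) {
    fit <- fit_smoothing_spline(t, y_line, spar = spar)
    expect_equal(fit$predict(t), y_line, tolerance = 1e-8)
  }
  y_cubic <- 0.01 * t^3 - 0.3 * t^2 + 2 * t + 5
  fit <- fit_smoothing_spline(t, y_cubic, lambda = 1e-12)
  expect_equal(fit$predict(t), y_cubic, tolerance = 1e-6)
})

test_that("light smoothing recovers a noisy sinusoid", {
  set.seed(41)
  t <- seq(0, 48, length.out = 200)
  truth <- sin(2 * pi * t / 24)
  fit <- fit_smoothing_spline(t, truth + rnorm(200, 0, 0.01), spar = 0.05)
  rmse <- sqrt(mean((fit$predict(t) - truth)^2))
  expect_lt(rmse, 0.02)
})

test_that("fewer than 4 points fall back to linear interpolation, flagged", {
  expect_warning(fit <- fit_smoothing_spline(c(0, 1, 2), c(1, 3, 5)),
                 "linear")
  expect_equal(fit$method, "linear")
  expect_equal(fit$predict(1.5), 4)
})

test_that("gap masking: dense series unmasked, 8-h gap masked, 6-h gap filled", {
  obs_t <- seq(0, 48, by = 2)
  fit <- fit_smoothing_spline(obs_t, 2 + 0 * obs_t)
  g <- resample_to_grid(fit, obs_t, rep(0.1, length(obs_t)))
  expect_true(all(g$mask == "observed"))

  # remove observations to create an 8-h gap (10 -> 18)
  obs_t2 <- setdiff(obs_t, c(12, 14, 16))
  g2 <- resample_to_grid(fit, obs_t2, rep(0.1, length(obs_t2)))
  expect_equal(g2$mask[g2$time_h %in% c(12, 14, 16)], rep("masked", 3))
  expect_equal(g2$mask[g2$time_h == 10], "observed")

  # a 6-h gap exactly (10 -> 16) is filled: boundary inclusive
  obs_t3 <- setdiff(obs_t, c(12, 14))
  g3 <- resample_to_grid(fit, obs_t3, rep(0.1, length(obs_t3)))
  expect_true(all(g3$mask == "observed"))
})

test_that("grid points take the sd of the nearest observation", {
  obs_t <- c(0, 2, 4, 6, 8)
  sds <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fit <- fit_smoothing_spline(obs_t, c(1, 2, 3, 4, 5))
  g <- resample_to_grid(fit, obs_t, sds, step = 2)
  expect_equal(g$sd, sds)
})

test_that("trapezoid cumulation is exact for constant and linear series", {
  t <- seq(0, 120, by = 2)
  s_const <- data.frame(time_h = t, value = 1, sd = 0, mask = "observed")
  expect_equal(cumulate_trapezoid(s_const, c(0, 120))$total, 120)

  a <- 0.3; b <- 0.02
  s_lin <- data.frame(time_h = t, value = a + b * t, sd = 0, mask = "observed")
  expect_equal(cumulate_trapezoid(s_lin, c(0, 120))$total,
               a * 120 + b * 120^2 / 2, tolerance = 1e-12)
})

test_that("a masked interior run integrates as its linear bridge", {
  t <- seq(0, 24, by = 2)
  v <- 5 + 0.5 * t
  masked <- t >= 8 & t <= 14
  s_masked <- data.frame(time_h = t, value = ifelse(masked, NA, v), sd = 0,
                         mask = ifelse(masked, "masked", "observed"))
  # same series with the masked run replaced by its linear bridge
  bridge <- approx(t[!masked], v[!masked], xout = t)$y
  s_bridged <- data.frame(time_h = t, value = bridge, sd = 0, mask = "observed")
  c1 <- cumulate_trapezoid(s_masked, c(0, 24))
  c2 <- cumulate_trapezoid(s_bridged, c(0, 24))
  expect_equal(c1$total, c2$total, tolerance = 1e-12)
  expect_gt(c1$fill_fraction, 0)
  expect_equal(c2$fill_fraction, 0)
})

test_that("an entirely masked window is an error", {
  t <- seq(0, 24, by = 2)
  s <- data.frame(time_h = t, value = NA_real_, sd = 0, mask = "masked")
  expect_error(cumulate_trapezoid(s, c(0, 24)), "fewer than 2")
})

test_that("replicate infill reproduces the replicate-mean increment exactly", {
  t <- seq(0, 24, by = 2)
  gap <- t >= 8 & t <= 16
  target <- data.frame(time_h = t, value = ifelse(gap, NA, 3), sd = 0.1,
                       mask = ifelse(gap, "masked", "observed"))
  # two replicates contributing 8 and 12 units over the flank-to-flank window
  mk_rep <- function(level) {
    data.frame(time_h = t, value = level, sd = 0.1, mask = "observed")
  }
  # flanks at 6 and 18 (12 h): constant levels 8/12 and 12/12 per hour
  r1 <- mk_rep(8 / 12); r2 <- mk_rep(12 / 12)
  filled <- replicate_mean_infill(target, list(r1, r2), c(8, 16))
  expect_true(all(filled$mask[gap] == "gap-filled-replicate"))
  got <- cumulate_trapezoid(filled, c(6, 18))$total
  want <- mean(c(cumulate_trapezoid(r1, c(6, 18))$total,
                 cumulate_trapezoid(r2, c(6, 18))$total))
  expect_equal(got, want, tolerance = 1e-12)

  # equal replicates: increment is their common value
  f2 <- replicate_mean_infill(target, list(mk_rep(10 / 12), mk_rep(10 / 12)),
                              c(8, 16))
  expect_equal(cumulate_trapezoid(f2, c(6, 18))$total, 10, tolerance = 1e-12)

  # no covering replicate: unchanged, with a warning
  r_gappy <- data.frame(time_h = t, value = NA_real_, sd = 0.1, mask = "masked")
  expect_warning(f3 <- replicate_mean_infill(target, list(r_gappy), c(8, 16)),
                 "no replicate covers")
  expect_true(all(f3$mask[gap] == "masked"))
})

test_that("MC uncertainty matches the closed-form weight-vector variance", {
  t <- seq(0, 24, by = 2)
  s0 <- data.frame(time_h = t, value = 2, sd = 0, mask = "observed")
  mc0 <- mc_cumulative_uncertainty(s0, c(0, 24), n = 200, seed = 1)
  expect_equal(mc0$mc_sd, 0)

  sig <- 0.4
  s <- data.frame(time_h = t, value = 2, sd = sig, mask = "observed")
  mc <- mc_cumulative_uncertainty(s, c(0, 24), n = 1000, seed = 7)
  h <- 2
  m <- length(t)
  closed_form <- sig * h * sqrt((m - 2) + 2 * 0.25) # trapezoid weight vector
  expect_equal(mc$mc_sd, closed_form, tolerance = 0.1)

  # determinism under a fixed seed
  mc2 <- mc_cumulative_uncertainty(s, c(0, 24), n = 1000, seed = 7)
  expect_identical(mc$totals, mc2$totals)

  # MC mean converges to the deterministic total within 3 mc_sd / sqrt(n)
  det_total <- cumulate_trapezoid(s, c(0, 24))$total
  expect_lt(abs(mean(mc$totals) - det_total), 3 * mc$mc_sd / sqrt(1000))
})
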