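# Classical and permutational ANOVA for the 2x2 drought x land-use design.

test_that("a constant response returns F = 0 with a degenerate flag", {
  d <- design_2x2(2)
  got <- two_way_anova(rep(5, 8), d$a, d$b)
  expect_true(all(got$degenerate))
  expect_true(all(got$F == 0))
})

test_that("F values equal textbook sums-of-squares arithmetic", {
  # cell means (0, 0, 0, 10), two replicates per cell at mean -/+ 0.5
  d <- design_2x2(2)
  cell_means <- c(0, 0, 0, 10)[match(paste(d$a, d$b),
                                     unique(paste(d$a, d$b)))]
  y <- cell_means + rep(c(-0.5, 0.5), 4)
  got <- two_way_anova(y, d$a, d$b)

  # independent textbook arithmetic on the chosen 8 numbers
  grand <- mean(y)
  ss_a <- sum(tapply(y, d$a, function(v) length(v) * (mean(v) - grand)^2))
  ss_b <- sum(tapply(y, d$b, function(v) length(v) * (mean(v) - grand)^2))
  cells <- paste(d$a, d$b)
  ss_cells <- sum(tapply(y, cells, function(v) length(v) * (mean(v) - grand)^2))
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - ave(y, cells))^2)
  ms_res <- ss_res / 4
  expect_equal(got$F, c(ss_a / ms_res, ss_b / ms_res, ss_ab / ms_res),
               tolerance = 1e-10)
  expect_true(all(got$F > 0))

  # location invariance: shifting all values leaves every F unchanged
  got_shift <- two_way_anova(y + 100, d$a, d$b)
  expect_equal(got_shift$F, got$F, tolerance = 1e-10)
})

test_that("classical F equals a reference least-squares fit on random designs", {
  set.seed(61)
  for (i in 1:5) {
    d <- design_2x2(3)
    y <- rnorm(12)
    got <- two_way_anova(y, d$a, d$b)
    ref <- anova(lm(y ~ a * b, data = data.frame(y = y, a = d$a, b = d$b)))
    expect_equal(got$F, ref$`F value`[1:3], tolerance = 1e-10)
    expect_equal(got$p_classical, ref$`Pr(>F)`[1:3], tolerance = 1e-10)
  }
})

test_that("a single-level factor is an error", {
  expect_error(two_way_anova(rnorm(8), rep("x", 8), rep(c("u", "v"), 4)),
               "fewer than 2 levels")
})

test_that("permutation p-values are reproducible under a fixed seed", {
  d <- design_2x2(3)
  set.seed(62)
  y <- rnorm(12)
  p1 <- permutation_anova(y, d$a, d$b, n_perm = 500, seed = 9)
  p2 <- permutation_anova(y, d$a, d$b, n_perm = 500, seed = 9)
  expect_identical(p1$p_exact, p2$p_exact)
  # main effects enumerate (choose(6,3)^2 = 400 distinct reassignments)
  expect_equal(p1$method[1:2], c("enumeration", "enumeration"))
  expect_equal(p1$n_perm[1:2], c(400, 400))
})

test_that("perfectly separated groups reach the enumeration's minimal p", {
  # drought shifts every value far beyond the noise: F_obs is the maximum
  # over all label reassignments, so p equals the minimal attainable value
  d <- design_2x2(3)
  set.seed(63)
  y <- rnorm(12, sd = 0.01) + ifelse(d$a == "drought", 100, 0)
  got <- permutation_anova(y, d$a, d$b, terms = "factor_a")

  # brute-force oracle: enumerate all within-stratum reassignments with
  # utils::combn and recompute F via lm for each
  strata <- split(seq_along(d$b), d$b)
  combos_by_stratum <- lapply(strata, function(pos) {
    utils::combn(pos, 3, simplify = FALSE)
  })
  f_of <- function(labels) {
    anova(lm(y ~ a * b,
             data = data.frame(y = y, a = labels, b = d$b)))$`F value`[1]
  }
  fs <- c()
  for (c1 in combos_by_stratum[[1]]) {
    for (c2 in combos_by_stratum[[2]]) {
      lab <- rep("drought", 12)
      lab[c(c1, c2)] <- "control"
      fs <- c(fs, f_of(lab))
    }
  }
  f_obs <- f_of(d$a)
  # relative tie tolerance: F values here are huge and float rounding on the
  # complement reassignment must still count as a tie
  p_oracle <- mean(fs >= f_obs * (1 - 1e-8))
  p_min <- mean(fs >= max(fs) * (1 - 1e-8))
  expect_equal(got$p_exact, p_oracle, tolerance = 1e-12)
  expect_equal(got$p_exact, p_min, tolerance = 1e-12)
})

test_that("sampled permutation p matches enumerated p within binomial error", {
  d <- design_2x2(3)
  set.seed(64)
  y <- rnorm(12) + ifelse(d$a == "drought", 1.2, 0)
  enum <- permutation_anova(y, d$a, d$b, terms = "factor_a")
  samp <- permutation_anova(y, d$a, d$b, terms = "factor_a",
                            n_perm = 4000, seed = 5, enumerate_limit = 1)
  expect_equal(samp$method, "sampling")
  se <- sqrt(enum$p_exact * (1 - enum$p_exact) / 4000)
  expect_lt(abs(samp$p_exact - enum$p_exact), 4 * se + 2 / 4000)
})

test_that("an unbalanced design is refused by the permutation engine", {
  d <- design_2x2(3)
  expect_error(permutation_anova(rnorm(11), d$a[-1], d$b[-1]),
               "balanced")
})
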