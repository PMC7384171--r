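# Classical two-way ANOVA F statistics and a permutation ANOVA with exact
# p-values for drought x land-use effects on cumulative outcomes.
#
# Permutation scheme (fixed and documented, with n_perm and seed surfaced):
# main effects permute the tested factor's assignment within levels of the
# other factor (restricted permutation, equivalent to permuting responses
# within strata); the interaction permutes residuals of the additive fit
# (Freedman-Lane). When the distinct-permutation count of a restricted test
# is at most `enumerate_limit` (and the tested factor has two levels), the
# permutation distribution is fully enumerated instead of sampled.

# balanced-design sums of squares -> F for (A, B, AB); idx* are index lists
.f_balanced <- function(y, idxA, idxB, idxCell, dfA, dfB, dfAB, df_res) {
  N <- length(y)
  G <- sum(y)
  ssT <- sum(y^2) - G^2 / N
  lev_ss <- function(idx) {
    sum(vapply(idx, function(ix) sum(y[ix])^2 / length(ix), numeric(1))) - G^2 / N
  }
  ssA <- lev_ss(idxA)
  ssB <- lev_ss(idxB)
  ssCells <- lev_ss(idxCell)
  ssAB <- ssCells - ssA - ssB
  ss_res <- ssT - ssCells
  ms_res <- ss_res / df_res
  if (ms_res <= 0) {
    # degenerate (zero residual variance): define F as Inf unless the term SS
    # is also zero, in which case 0
    f <- function(ss, df) if (ss / df > 0) Inf else 0
    return(c(A = f(ssA, dfA), B = f(ssB, dfB), AB = f(ssAB, dfAB)))
  }
  c(A = (ssA / dfA) / ms_res, B = (ssB / dfB) / ms_res,
    AB = (ssAB / dfAB) / ms_res)
}

.design_indices <- function(a, b) {
  a <- factor(a)
  b <- factor(b)
  if (nlevels(a) < 2) stop("factor_a has fewer than 2 levels")
  if (nlevels(b) < 2) stop("factor_b has fewer than 2 levels")
  cell <- interaction(a, b, drop = FALSE)
  counts <- table(cell)
  list(a = a, b = b,
       idxA = split(seq_along(a), a),
       idxB = split(seq_along(b), b),
       idxCell = split(seq_along(a), cell),
       balanced = length(unique(as.integer(counts))) == 1,
       min_cell = min(counts),
       dfA = nlevels(a) - 1, dfB = nlevels(b) - 1,
       dfAB = (nlevels(a) - 1) * (nlevels(b) - 1),
       df_res = length(a) - nlevels(a) * nlevels(b))
}

#' Classical two-way ANOVA F statistics
#'
#' Fixed-effects ANOVA of `values ~ factor_a * factor_b` (sequential sums of
#' squares via [stats::aov()]), returning the F statistic and F-distribution
#' p-value per term. A completely constant response is returned as F = 0 with
#' a degenerate-data flag rather than 0/0.
#'
#' @param values Numeric response (e.g. cumulative efflux per monolith).
#' @param factor_a,factor_b Factors (e.g. drought treatment and land use).
#' @param term_names Labels for the two main effects in the output.
#' @return data.frame: `term`, `df`, `F`, `p_classical`, `degenerate`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          term_names = c("factor_a", "factor_b")) {
  di <- .design_indices(factor_a, factor_b)
  if (di$min_cell < 2) {
    stop("two_way_anova: interaction needs >= 2 replicates per cell")
  }
  terms_out <- c(term_names, "interaction")
  if (stats::var(values) == 0) {
    return(data.frame(term = terms_out, df = c(di$dfA, di$dfB, di$dfAB),
                      F = 0, p_classical = 1, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(values ~ a * b, data = data.frame(values = values,
                                                      a = di$a, b = di$b))
  tab <- summary(fit)[[1]]
  data.frame(term = terms_out, df = tab[1:3, "Df"],
             F = tab[1:3, "F value"], p_classical = tab[1:3, "Pr(>F)"],
             degenerate = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

# all distinct within-strata reassignments for a 2-level tested factor:
# returns a list of permuted index vectors `perm` such that y[perm] realises
# the reassignment (responses permuted, design fixed)
.enumerate_restricted <- function(strata_idx, n_level1) {
  per_stratum <- lapply(seq_along(strata_idx), function(s) {
    pos <- strata_idx[[s]]
    k <- n_level1[[s]]
    combos <- utils::combn(length(pos), k, simplify = FALSE)
    lapply(combos, function(cb) c(pos[cb], pos[-cb]))
  })
  out <- list(integer(0))
  for (ps in per_stratum) {
    out <- unlist(lapply(out, function(acc) {
      lapply(ps, function(p) c(acc, p))
    }), recursive = FALSE)
  }
  out
}

#' Permutation ANOVA with exact p-values
#'
#' Permutation test of both main effects and the interaction in a balanced
#' two-way design. Main effects use restricted permutation (within levels of
#' the other factor); the interaction uses Freedman-Lane residual
#' permutation of the additive fit. p_exact = (1 + #\{F* >= F_obs\}) /
#' (1 + n_perm) for sampled permutations, or the exact tail proportion under
#' full enumeration (used when the distinct-permutation count is at most
#' `enumerate_limit`).
#'
#' @inheritParams two_way_anova
#' @param n_perm Number of sampled permutations per term (default 5000).
#' @param seed RNG seed (caller's RNG state is restored).
#' @param terms Subset of `c("factor_a", "factor_b", "interaction")` to test.
#' @param enumerate_limit Enumerate fully when at most this many distinct
#'   permutations exist (default 20000).
#' @return data.frame: `term`, `F`, `p_classical`, `p_exact`, `n_perm`,
#'   `method`, `seed`.
#' @export
permutation_anova <- function(values, factor_a, factor_b, n_perm = 5000,
                              seed = NULL,
                              terms = c("factor_a", "factor_b", "interaction"),
                              term_names = c("factor_a", "factor_b"),
                              enumerate_limit = 20000) {
  terms <- match.arg(terms, several.ok = TRUE)
  di <- .design_indices(factor_a, factor_b)
  if (!di$balanced) {
    stop("permutation_anova: requires a balanced design (equal cell counts)")
  }
  if (di$min_cell < 2) {
    stop("permutation_anova: interaction needs >= 2 replicates per cell")
  }
  y <- values
  f_obs <- .f_balanced(y, di$idxA, di$idxB, di$idxCell,
                       di$dfA, di$dfB, di$dfAB, di$df_res)
  classical <- two_way_anova(values, factor_a, factor_b, term_names)
  tol <- 1e-8 * max(1, abs(f_obs))

  perm_main <- function(which_f) {
    # strata = levels of the *other* factor; tested factor's labels are
    # reassigned within strata, realised as permuting y within strata
    tested <- if (which_f == "A") di$a else di$b
    strata <- if (which_f == "A") di$idxB else di$idxA
    stat <- function(yy) .f_balanced(yy, di$idxA, di$idxB, di$idxCell,
                                     di$dfA, di$dfB, di$dfAB,
                                     di$df_res)[[which_f]]
    n_distinct <- prod(vapply(strata, function(pos) {
      choose(length(pos), sum(tested[pos] == levels(tested)[1]))
    }, numeric(1)))
    if (nlevels(tested) == 2 && n_distinct <= enumerate_limit) {
      n1 <- lapply(strata, function(pos) sum(tested[pos] == levels(tested)[1]))
      # reorder each stratum's positions so level-1 slots come first
      strata_ord <- lapply(strata, function(pos) {
        c(pos[tested[pos] == levels(tested)[1]],
          pos[tested[pos] != levels(tested)[1]])
      })
      perms <- .enumerate_restricted(strata_ord, n1)
      fs <- vapply(perms, function(p) {
        yy <- y
        yy[unlist(strata_ord)] <- y[p]
        stat(yy)
      }, numeric(1))
      list(p = mean(fs >= f_obs[[which_f]] - tol), n = length(fs),
           method = "enumeration")
    } else {
      fs <- vapply(seq_len(n_perm), function(i) {
        yy <- y
        for (pos in strata) yy[pos] <- y[sample(pos)]
        stat(yy)
      }, numeric(1))
      list(p = (1 + sum(fs >= f_obs[[which_f]] - tol)) / (1 + n_perm),
           n = n_perm, method = "sampling")
    }
  }

  perm_interaction <- function() {
    # Freedman-Lane: permute residuals of the additive (main-effects) fit
    N <- length(y)
    grand <- mean(y)
    effA <- vapply(di$idxA, function(ix) mean(y[ix]) - grand, numeric(1))
    effB <- vapply(di$idxB, function(ix) mean(y[ix]) - grand, numeric(1))
    fitted <- grand + effA[as.integer(di$a)] + effB[as.integer(di$b)]
    e <- y - fitted
    stat <- function(yy) .f_balanced(yy, di$idxA, di$idxB, di$idxCell,
                                     di$dfA, di$dfB, di$dfAB, di$df_res)[["AB"]]
    if (factorial(N) <= enumerate_limit) {
      perms <- .permutations_all(N)
      fs <- vapply(perms, function(p) stat(fitted + e[p]), numeric(1))
      list(p = mean(fs >= f_obs[["AB"]] - tol), n = length(fs),
           method = "enumeration")
    } else {
      fs <- vapply(seq_len(n_perm), function(i) stat(fitted + e[sample(N)]),
                   numeric(1))
      list(p = (1 + sum(fs >= f_obs[["AB"]] - tol)) / (1 + n_perm),
           n = n_perm, method = "sampling")
    }
  }

  res <- .with_seed(seed, {
    rows <- list()
    if ("factor_a" %in% terms) {
      r <- perm_main("A")
      rows[[length(rows) + 1]] <- data.frame(
        term = term_names[1], F = f_obs[["A"]],
        p_classical = classical$p_classical[1],
        p_exact = r$p, n_perm = r$n, method = r$method,
        stringsAsFactors = FALSE)
    }
    if ("factor_b" %in% terms) {
      r <- perm_main("B")
      rows[[length(rows) + 1]] <- data.frame(
        term = term_names[2], F = f_obs[["B"]],
        p_classical = classical$p_classical[2],
        p_exact = r$p, n_perm = r$n, method = r$method,
        stringsAsFactors = FALSE)
    }
    if ("interaction" %in% terms) {
      r <- perm_interaction()
      rows[[length(rows) + 1]] <- data.frame(
        term = "interaction", F = f_obs[["AB"]],
        p_classical = classical$p_classical[3],
        p_exact = r$p, n_perm = r$n, method = r$method,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  res$seed <- if (is.null(seed)) NA_integer_ else seed
  res
}

# all permutations of 1..n (only called for tiny n)
.permutations_all <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .permutations_all(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (i in 0:(n - 1)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = i)
    }
  }
  out
}
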