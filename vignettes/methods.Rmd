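---
title: "Methods: from raw isotopologue streams to tracer budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw isotopologue streams to tracer budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science and the numerical choices behind
`isopulse`: what each stage computes, which assumptions it makes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## 1. Measurement model

A steady-state flow-through chamber of footprint $A$ (default: a 4.5-cm
tube, $A = \pi \cdot 0.0225^2\,\mathrm{m^2}$) is flushed at a constant
volumetric flow (default 170 ml/min). An automated multiplexer routes one
line at a time to the isotope analyzer: 100 s of buffer-inlet air, 250 s of
chamber-outlet air, 100 s of inlet air again, cycling over all chambers,
with three calibration gases (400, 1500, 5000 ppm total CO₂ of known ¹³C
atom fraction) measured after each sweep (about every 2 h).

Flux and source-composition equations:

$$\mathrm{SR} = \frac{f\,(\mathrm{CO_2}_{out} - \mathrm{CO_2}_{in})}{A},
\qquad
\chi(^{13}C) = \frac{^{13}\mathrm{CO_2}}{^{13}\mathrm{CO_2} + {}^{12}\mathrm{CO_2}},$$

$$\chi_{SR} = \frac{\chi_{out}\,\mathrm{CO_2}_{out} - \chi_{in}\,\mathrm{CO_2}_{in}}
                   {\mathrm{CO_2}_{out} - \mathrm{CO_2}_{in}},
\qquad
\chi E = \chi_{SR} - \chi_{SR}^{NA},
\qquad
\mathrm{abs^{13}C} = \chi E \cdot \mathrm{SR}.$$

Assumptions: the chamber is at steady state (inlet–outlet difference
reflects the soil flux); total CO₂ is the two-isotopologue sum (¹²CO₂ +
¹³CO₂; other isotopologues are ignored, consistently on both sides of every
ratio); concentrations are dry-air mole fractions (no water-vapour or
pressure-broadening corrections). The volumetric flow is converted to molar
flow at the mass-flow meter's reference conditions, default 273.15 K /
101.325 kPa (22.414 L/mol), both configurable, since flow meters report at
standard rather than ambient conditions.

### Segmentation choices

* **Dead band (default 30 s, configurable).** Multiplexed lines need
  flushing after a switch; the first 30 s of every window are discarded.
  The 250-s outlet window retains ample data (220 samples at 1 Hz).
* **Inlet pooling.** The outlet window is framed by two inlet windows; they
  are pooled with equal weight (mean of the two window means; pooled sd
  combines within-window variance and the between-window separation). Under
  a stationary inlet this is unbiased and simpler than time interpolation.
* Windows are half-open $[start, end)$, timestamps UTC; duplicate
  (time, line) records are dropped and counted.

## 2. Calibration

Each calibration cycle yields, per isotopologue, an ordinary least-squares
line $true = span \cdot measured + offset$ — fitted in this direction so
that application is a single affine map. Between successive cycles, span and
offset are interpolated linearly in time: this bounds instrument drift while
degrading gracefully to per-cycle constants when cycles are dense. Outside
the first/last cycle the nearest curve applies; records farther than 6 h
(configurable) from any calibration are flagged stale. Calibrated records
carry a flag, and re-applying calibration is an error — the affine map is
not idempotent, and silent double application is a classic processing bug.
Corrected values outside the nominal validity ranges (400–5000 ppm for
¹²CO₂, 4–50 ppm for ¹³CO₂) are flagged, not dropped.

## 3. Uncertainty propagation and QC

Standard deviations of window means, flow, and the natural-abundance
baseline propagate through each equation by first-order Taylor expansion
with closed-form partials, assuming independent inputs. In particular the
covariance between SR and $\chi E$ in the tracer-efflux product is set to
zero: each measured variable is propagated independently, which keeps the
per-equation error budgets interpretable. The tests verify the first-order
regime claim: propagated sds agree with large-sample Monte-Carlo oracles
within 5% when every input CV ≤ 0.2.

QC rules: observations with SR < 0 or $\chi E$ < 0 are excluded as
`excluded_negative`; observations with CV(SR) > 1 or CV($\chi E$) > 1 as
`excluded_cv`. Both CV rules are applied per observation. The boundary
CV = 1 exactly is retained (strict inequality). The mixing equation is only
attempted when the chamber gradient exceeds 5 µmol/mol (configurable):
smaller gradients make the division numerically explosive, and an explicit
floor makes the failure deterministic instead of leaving it to the CV
filter. Mixing results outside the sanity interval $[-0.1, 1.1]$ are
flagged — the mixing end-member may legitimately fall outside
$[\chi_{in}, \chi_{out}]$, but not that far.

The natural abundance $\chi_{SR}^{NA}$ is the mean of valid pre-label
observations (default: the 48 h before the label start). It is never
defaulted: with no valid pre-label observation the monolith fails hard,
because every downstream excess quantity would silently inherit a wrong
baseline.

## 4. Gridding and cumulation

Irregular per-monolith series are fitted with penalized cubic smoothing
splines (`spar = 0.05`: light, near-interpolating smoothing; the smoothing
parameter is exposed in the configuration). The spline is evaluated on a
regular grid (default 2 h). Grid points inside observation gaps longer than
6 h are masked — splines are not trusted to extrapolate across long gaps —
with the 6-h boundary inclusive (a gap of exactly 6 h is filled). Per-point
sds are taken from the nearest raw observation: splines smooth values, not
uncertainties, and this choice is conservative and simple. With fewer than
4 observations the series falls back to linear interpolation, flagged.

Cumulation uses the trapezoid rule. Interior masked runs are bridged
linearly between the flanking unmasked points (for the trapezoid rule this
is identical to integrating over the gappy abscissae directly, which is how
it is implemented — the integral is a fixed linear functional of the
supported points). The share of a window covered by bridged cells or
uncovered edges is reported as `fill_fraction`. A window with fewer than two
supported points is an error, never a fabricated total.

The replicate-mean rule generalizes a one-off repair: when a gap exceeds
the spline limit and treatment replicates cover it, the gap's cumulative
increment is set to the mean of the replicates' increments over the same
flank-to-flank window, by placing the masked points at the constant level
that reproduces that increment exactly under the trapezoid rule. It is
applied generically to any over-long gap with covering replicates, since
restricting it to one historical gap would not be reusable behaviour.

Monte-Carlo uncertainty: 1000 series are resampled with each supported grid
point independently normal(value, sd) and integrated identically; the sd
and central 95% interval of the totals are reported. Draws are independent
across grid points — temporal correlation of analyzer errors is not
modelled, so these intervals are tight lower bounds under positively
correlated errors. Because the integral is linear in the points, the
resampling reduces to a weighted sum, and the implementation exploits that.

Default windows: 120 h after label end (the chase), 72 h after rewetting.
Both are configurable; 72 h is used even though summary tables elsewhere
have been headed with 70 h — the two are close and the choice is explicit
in the configuration rather than buried.

## 5. Kinetics and partitioning

The dark-pulse test (labelling with a darkened chamber, so no
photosynthetic uptake) isolates physical back-diffusion of tracer from soil
pores. A single exponential $r(t) = r_0 e^{-kt}$ is fitted by nonlinear
least squares (Levenberg–Marquardt), initialized from a log-linear
regression on the positive values; MRT $= 1/k$. Multi-pool variants are out
of scope for this diagnostic fit. A non-decaying series raises a typed
error carrying the log-linear fallback estimate, rather than returning a
pseudo-fit with $k \to 0$.

rel¹³C is the cumulative tracer efflux divided by the monolith's total
assimilated ¹³C ($U$, shoots + roots, measured externally and supplied as
input — this package never computes it). Group summaries report mean ± SD
across replicates and the drought percent change
$100\,(1 - \bar{x}_{drought}/\bar{x}_{control})$, signed so that positive
means reduction under drought.

## 6. Treatment statistics

Classical two-way ANOVA (sequential sums of squares via `stats::aov`)
reports effect-size F values. Exact p-values come from a permutation ANOVA
with a fixed, documented scheme: main effects permute the tested factor's
assignment within levels of the other factor (restricted permutation);
the interaction permutes residuals of the additive fit (Freedman–Lane).
When the distinct-permutation count is at most 20,000 — as in the 2×2×3
design, where it is $\binom{6}{3}^2 = 400$ — the distribution is fully
enumerated and the p-value is the exact tail proportion (the observed
assignment included, so p ≥ 1/400); otherwise p = (1 + #{F* ≥ F}) /
(1 + n_perm) over 5000 sampled permutations, which cannot be zero.
Sequential-stopping schemes exist but a fixed-n scheme with an exposed seed
is reproducible by construction. The permutation engine requires a balanced
design (its sums of squares use the balanced closed forms); the classical
ANOVA does not.

## 7. Leachates

Dissolved organic carbon amounts are concentration × volume with Taylor
sds. Tracer-derived DO¹³C is the excess of the sample's ¹³C atom fraction
over the natural-abundance baseline — the mean over unlabelled monoliths of
the same sampling occasion — times the DOC mass (small-enrichment
approximation). An exact-mass switch instead converts via moles of C and
the ¹³C molar mass; it rescales levels by the molar-mass ratio
(≈ 13.003/12.02) but cancels in all drought/land-use contrasts, which is
why the plain atom-fraction bookkeeping is the default.

## 8. The synthetic-data generator

`generate_scenario()` is a forward model of the study conditions, not a
curve sampler: it writes the same raw multiplexed stream the instrument
would produce, and the pipeline must undo everything the generator did.

Ground truth per monolith:

* $SR(t) = B\,m(t)\,(1 + a_d(t) \sin(\text{diel}))\,\text{birch}(t)$ with
  baseline $B$ (defaults 3.5 / 2.5 µmol m⁻² s⁻¹ for managed / abandoned,
  with 5% lognormal between-monolith jitter), drought multiplier
  $m_d = 0.5$ while the drought is active, diel amplitude 0.3 peaking at
  14:00 (damped ×0.05 under active drought, encoding the loss of diel
  fluctuations in dry soil), and a rewetting pulse
  $1 + (P-1)e^{-(t-t_{rw})/\tau_b}$ with $P = 3$, $\tau_b = 12$ h — a Birch
  pulse up to three times control decaying within ~2 days.
* Tracer efflux: a two-pool kernel
  $U R\,[w_f k_f e^{-k_f\tau} + w_s k_s e^{-k_s\tau}]$ starting
  $\delta = 1.5$ h after label start, with $w_f = 0.7$,
  $k_f = 1/12\,h^{-1}$, $k_s = 1/96\,h^{-1}$ — the minimal shape giving
  rapid appearance, a multi-day decline and diel modulation. The total
  respired fraction $R$ (default 0.15) scales the kernel: the kernel alone
  integrates to ~0.91 of $U$ over 120 h, which would be far outside the
  observed range of belowground tracer recovery, so the pool weights set
  the *shape* and $R$ sets the *amount* (120-h control fractions land near
  13–14%, inside the plausible 7–19% band). Drought monoliths additionally
  remobilize a fraction $w_{rw} = 0.05$ of $U$ at rewetting with a 12-h
  decay, so the rewetting window respires more residual label than
  controls; $R + w_{rw} \le 1$ is enforced so cumulated tracer can never
  exceed uptake.
* Outlet concentrations are reconstructed by inverting the flux and mixing
  equations, Gaussian analyzer noise is added (defaults 0.200 / 0.010
  µmol/mol), and the *inverse* of the configured span–offset distortion
  (defaults: span 0.98 / 0.97, offset 5 / 0.2 µmol/mol) is applied, so the
  pipeline's calibration stage must recover the truth. Scenarios implying
  source or outlet atom fractions outside [0, 1] are rejected with a
  diagnostic.
* The analytic windowed integrals in the truth record are computed by
  adaptive quadrature split at the known kinks (tracer onset, rewetting),
  independent of the pipeline's spline/trapezoid path.

What the generator does **not** emulate: photosynthesis and the labelling
chamber itself ($U$ is assigned, not grown), soil-moisture dynamics,
temporally correlated analyzer drift between calibrations, leachate
hydrology (volumes and concentrations are drawn around group means), and
between-monolith variance structure beyond lognormal baseline/uptake
jitter. Passing tests therefore demonstrate correctness of the *reduction
chain* under realistic magnitudes and noise, not that real soils follow
two-pool kinetics.

All randomness flows from the single scenario seed; identical seeds give
identical streams.

## 9. Problem sizes and tolerances used in the tests

The suite runs scaled study conditions chosen to exercise every code path
at desk scale: closure tests use one monolith over ~140 h at zero noise
(SR reproduced to better than 1e-6 relative; 120-h tracer fractions to
1e-3, the residual being spline rounding of the tracer-onset corner);
recovery tests use 6 monoliths over ~170 h at default noise (the 0.5
drought multiplier is summarized as a 50 ± 5% reduction); the type-I-error
simulation uses 500 null 2×2×3 datasets under full enumeration; Taylor
sds are checked against 10⁶-draw Monte-Carlo oracles. The acceptance
script runs the full 24-monolith-equivalent default scenario (12 monoliths
per campaign structure, ~10 days of 2-s samples).

## 10. Known limitations

* Monoliths in one run share label and rewetting times (the generator's
  schedule); per-monolith labelling days would need per-monolith windows.
* MC intervals ignore temporal error correlation (see §4).
* The permutation engine is restricted to balanced designs.
* The leachate module starts at concentrations and atom fractions;
  instrument-side processing (peak areas, standards) is out of scope.
* δ-notation output is deliberately absent: all isotopic bookkeeping is in
  atom fractions, which remain well-behaved at enrichment levels where the
  δ scale becomes awkward.
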