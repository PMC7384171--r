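# isopulse

Data reduction for continuous, chamber-based measurements of soil
respiration and its carbon isotopic composition after **¹³CO₂ pulse
labelling**. The package targets experiments in which intact soil–vegetation
monoliths (here: managed vs. abandoned grassland under a drought/rewetting
manipulation) are labelled with ¹³CO₂ for ~75 min and the fate of the fresh
photoassimilates is traced in the soil CO₂ efflux of steady-state
flow-through chambers multiplexed to an isotope laser spectrometer.

It is written for ecosystem ecologists and biogeochemists who need the full
chain from a raw analyzer stream to treatment statistics, reproducibly and
with honest uncertainties.

## The model

Each measurement cycle yields inlet and outlet isotopologue concentrations
(¹²CO₂, ¹³CO₂, in µmol/mol). Soil respiration of a chamber of footprint *A*
flushed at molar flow *f* is

    SR = f · (CO₂_out − CO₂_in) / A            [µmol CO₂ m⁻² s⁻¹]

with total CO₂ = ¹²CO₂ + ¹³CO₂ and the atom fraction
χ(¹³C) = ¹³CO₂ / (¹³CO₂ + ¹²CO₂). Two-member mixing gives the isotopic
composition of the respired source,

    χ_SR = (χ_out·CO₂_out − χ_in·CO₂_in) / (CO₂_out − CO₂_in),

its excess above the pre-label natural abundance χE = χ_SR − χ_SR(NA), and
the absolute tracer efflux abs¹³C = χE · SR (reported in mg ¹³C m⁻² hr⁻¹).
Standard deviations propagate by first-order Taylor expansion; observations
with SR < 0, χE < 0, or a coefficient of variation above 1 are excluded.
Per-monolith series are aligned to a common 2-h grid with light smoothing
splines (gaps longer than 6 h are masked, not extrapolated), cumulated by
the trapezoid rule (linear bridging of gaps, optional replicate-mean infill),
and equipped with Monte-Carlo uncertainties (1000 resampled series).
Cumulative tracer efflux divided by the monolith's total assimilated ¹³C
(*U*, an external input) gives rel¹³C, the fraction of recent assimilates
respired belowground. Treatment effects are tested with classical two-way
ANOVA F statistics plus a permutation ANOVA with exact p-values; a
single-exponential fit to dark-pulse efflux quantifies the mean residence
time of physically back-diffusing tracer; leachate DOC/DO¹³C accounting
covers the dissolved pathway.

A forward model (`generate_scenario()`) emulates the whole experiment —
diel respiration, ~50% drought suppression, tracer appearance within 1.5 h,
a rewetting (Birch) pulse up to 3× control, analyzer noise of 200/10 ppb,
periodic span–offset calibration-gas cycles — and emits the analytic ground
truth next to the raw stream, so every stage is testable without any field
data.

## Worked example

```r
library(isopulse)
sc  <- synthetic_scenario(n_rep = 3, seed = 42)   # 2 land uses x 2 treatments x 3
sim <- generate_scenario(sc)
run <- run_pipeline(sim, pipeline_config(seed = 43, verbose = FALSE))
print(run)
make_report(run)
```

prints (abridged):

```
isopulse pipeline run: 1800 flux observations, 24 gridded series, 72 cumulative totals
QC: ok=1202, excluded_negative=132, excluded_cv=466, invalid_input=0

sr | chase window  [mol CO2 m-2]
  abandoned  control        1.12 +/- 0.061     n=3
  managed    control        1.51 +/- 0.0732    n=3
  abandoned  drought      0.5638 +/- 0.0327    n=3  (+49.7% vs control)
...
rel13c | rewet window  [fraction of uptake]
  abandoned  control    0.004198 +/- 0.00125   n=3
  abandoned  drought     0.05234 +/- 0.00033   n=3  (-1146.8% vs control)
    drought      F = 4405.913  p_F = 0.000  p_exact = 0.005 (enumeration, n_perm=400)
```

Reading: cumulated respiration over the 120-h chase is halved under drought
(+49.7% reduction vs. control); after rewetting, previously drought-exposed
monoliths respire an order of magnitude more residual tracer than controls
(the negative "reduction" is an increase), and the permutation ANOVA flags
the drought effect at the smallest p attainable under full enumeration of
the 2×2×3 design (p = 2/400 = 0.005).

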