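---
title: "Screening wheat traits with Morris sensitivity analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening wheat traits with Morris sensitivity analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitscreen)
```

`traitscreen` estimates, for each parameter of a wheat crop model, how much
yield (and seven other integrated outputs) would respond if breeding shifted
that trait within a plausible genetic range, and how that response depends on
site, season, sowing date, nitrogen fertilisation and atmospheric CO~2~. This
vignette documents the model, its assumptions, the tunable parameters, and
the design decisions taken where more than one defensible choice existed.

## 1. The factor space

### Registry and meta-parameters

The screened inventory is a registry of 103 parameters: 62 scalars and 41
"function" parameters (paired `x`/`y` vectors, counted as one parameter per
function). Twenty parameters whose independent variation would be
physically inconsistent — e.g. minimum, critical and maximum nitrogen
concentrations of one organ, where an independently raised minimum could
cross the maximum — are tied into 7 meta-parameters that move jointly, so
the screen has 103 − 20 + 7 = 90 independent factors
(`count_factors(wheat_registry())`).

Twenty registry entries are *active*: the surrogate simulator consumes them
and their causal role matches their name (phenology targets, photoperiod and
vernalisation sensitivities, radiation use efficiency, extinction
coefficient, specific leaf area, transpiration efficiency, water
extractability, grain set and filling parameters, CO~2~ modifiers, the
leaf-expansion water-deficit threshold). The remaining 83 are inert
placeholders named after conventional wheat-model parameters. They are not
dead weight: a correct screen must return exactly zero effect for them in
every environment, and the classification tests assert that. Nominal values
for the reference cultivar follow two printed anchors (vernalisation
sensitivity 1.5; thermal time to floral initiation 555 °Cd, photoperiod
sensitivity 3.0) with the rest chosen as a realistic reference wheat;
the registry file (`inst/extdata/registry.csv`) documents each entry.

Since the exact membership of the meta-parameter groups is not fully
published, the packaged groups (three organ-wise nitrogen-demand triplets,
leaf size, leaf appearance, root depth rates, soil-water bounds) are a
reconstruction that preserves the published arithmetic (7 groups, 20
members); only the bookkeeping, not the physiology of grouping, is on the
acceptance surface. Likewise, which function parameters used single-point
versus full-curve scaling is documented per entry as an assumption.

### Variation ranges

Every factor varies over a total width of 40 % of its nominal ν
(`apply_range_rule()`):

* unbounded: the symmetric multiplicative range (0.8 ν, 1.2 ν);
* hard-bounded (e.g. fractions in [0, 1]) where an endpoint is infeasible:
  the full 40 % width on the feasible side, (0.6 ν, ν) or (ν, 1.4 ν),
  clamped to the bounds;
* ν = 0: a zero-width range — the parameter is *fixed* and contributes no
  factor, rather than triggering a division by zero. The packaged registry
  contains no zero nominals, so its factor count stays 90.

Scalars are placed linearly inside their range
(`lower + level·(upper − lower)`), so level 0.5 recovers the nominal exactly
for symmetric ranges (for one-sided ranges the midpoint is deliberately the
range midpoint, not the nominal). Curves scale by the factor
0.8 + 0.4·level, applied to the whole `y` vector (full mode) or to one
designated `x` or `y` entry (point mode). A point perturbation of `x` that
would destroy strict monotonicity is rejected with an error naming the
parameter — an ill-posed perturbation should fail loudly, not be silently
re-sorted into a different curve.

## 2. The Morris design

The screen uses the elementary-effects method: `r` one-at-a-time
trajectories of g + 1 points on an n-level grid (n = 6 by default, levels
{0, 0.2, …, 1}), step Δ = n/(2(n − 1)) = 0.6. Δ is not dictated by the
method; this is the standard choice for even n, giving transitions that
straddle the grid symmetrically. Trajectories follow the classic
randomised-orientation construction: base point drawn from the lower n/2
levels, random per-factor direction, random factor order.

Dispersion of the design is maximised by generating a candidate pool
(`n_candidates`) and greedily selecting the `r`-subset with the largest sum
of pairwise inter-trajectory distances, the distance between two
trajectories being the summed Euclidean distances between all their row
pairs. A max–min criterion is an equally defensible alternative; the summed
criterion was chosen because it matches the classic space-filling variant of
the method and both agree on small enumerable cases (asserted in tests). The
default pool is 500 candidates for r = 100 and 30 for the desk preset;
selection cost grows quadratically in the pool, and pool sizes beyond a few
times `r` change the selected designs little.

Elementary effects divide the output change by the *signed* normalised step,
so μ\* is expressed in output units per full normalised range — i.e. per the
whole ±20 % genetic range of a trait — which is what makes "t/ha per trait
range" a meaningful breeding quantity. μ\* is the mean absolute effect, σ
the sample standard deviation of signed effects. Failed or missing
simulations propagate as missing effects with a warning; indices are then
computed over the available effects with the count reported, rather than
discarding the whole factor.

For comparisons across outputs and environments, outputs can be z-scored
within each environment before computing effects (standardized indices). A
zero-variance environment standardises to all zeros by convention — such an
environment carries no ranking information, and zeros keep downstream
aggregation finite.

## 3. The surrogate crop model

The simulator (`run_crop()`, daily loop in C++) is an explicitly simplified
process model in the APSIM lineage. It is *not* a reimplementation of any
full crop model: its purpose is to give every active trait the causal role
its name implies, so that screening behaviour is qualitatively right, while
staying small enough to audit. All forms are the standard ones:

* **Thermal time**: trapezoid cardinal response of daily mean temperature,
  base 0 °C, optimum 26 °C (peak 26 °Cd/day), maximum 34 °C
  (`thermal_time()`).
* **Phenology**: sowing → emergence (100 °Cd) → juvenile
  (`tt_end_of_juvenile`, gated by photoperiod and vernalisation) → floral
  initiation → flowering (`tt_floral_initiation`) → start of grain fill
  (`tt_start_grain_fill`) → maturity (580 °Cd of grain fill). The
  photoperiod factor is 1 − 0.002·`photop_sens`·(20 − P)², clamped to
  [0, 1], with P the civil-twilight day length (astronomical day length
  + 1.2 h, the convention in wheat phenology models); the vernalisation
  factor rises linearly with vernal days accumulated below 15 °C, scaled by
  `vern_sens`.
* **Water**: a four-layer bucket. Supply is Σ kl·(SW − LL_adj) over rooted
  layers, with the crop lower limit divided by `ll_modifier` (higher value →
  more extractable water). Demand is potential growth × VPD /
  `transp_eff_cf`; VPD is 0.75 of the Tetens saturation-pressure difference
  between daily extremes. The daily supply/demand ratio (capped at 1) is the
  water-stress factor for photosynthesis; an uncapped ratio drives leaf
  expansion through the `x_sw_demand_ratio` response. Rain cascades through
  layers with drainage above the drained upper limit; soil evaporation draws
  on the surface layer under sparse cover.
* **Growth**: interception 1 − e^(−k·LAI); daily gain is
  min(RUE-limited, transpiration-efficiency-limited) biomass, each with its
  CO~2~ modifier; leaf mass converts to area via `y_sla`; from floral
  initiation head (spike/rachis) growth competes with stem via `y_frac_pod`;
  senescence reduces LAI with age and water stress (dead leaf stays in
  aerial biomass; nothing detaches).
* **Grain**: number = `grains_per_gram_stem` × stem mass at flowering;
  daily fill = min(potential rate × temperature factor, assimilate +
  remobilisable reserve (25 % of stem + head at flowering)); size capped at
  `max_grain_size`; grain N transfers from the crop N pool with its own
  temperature response; protein % = 5.7 × grain N concentration.
* **Nitrogen**: a mineral soil pool with initial N, slow background
  mineralisation, and split fertiliser doses whose later applications are
  conditional (cumulative rainfall since sowing; plant-available water
  thresholds) — evaluated at runtime, so the same plan behaves differently
  across seasons. Crop N stress follows a critical-dilution band.

Internal audits are part of the contract and tested at tight tolerances:
season water balance closes to 10⁻⁶ mm, aerial biomass equals accumulated
gains to 10⁻⁹ t/ha, and yield ≡ grain number × grain size to 10⁻⁹. A crop
that never emerges or runs out of season is flagged `failed` with zero
yield.

Deliberate exclusions: frost/heat-shock mortality, tillering dynamics,
pests, phosphorus, and any attempt at numerical agreement with a full crop
model. Consequently the screen's *magnitudes* are surrogate magnitudes; what
carries over is the structure of trait × environment interactions (which
traits matter, where, and why).

## 4. Synthetic environments

`site_archetypes()` packages four Australian wheatbelt archetypes spanning
summer-dominant (Emerald, Narrabri), evenly-distributed (Yanco) and
winter-dominant (Merredin) rainfall, with profile plant-available water
capacities of 133.5, 217.5, 190.8 and 101.1 mm, sowing-time available water
of 132, 175, 99 and 39 mm (filled top-down), initial mineral N, and the
local split N schedules including their conditional triggers.

`generate_weather()` is a first-order stochastic generator: Bernoulli
rainfall occurrence with gamma amounts (shape 0.75), both modulated by one
seasonal harmonic whose phase encodes the rainfall pattern and whose
amplitude is calibrated so the May–November share matches the archetype's
seasonal/annual ratio; temperature as an annual sinusoid plus AR(1) noise;
radiation as a sinusoid plus white noise. The tabulated temperature and
radiation normals are growing-season (May–November) means, and the annual
sinusoids are solved to reproduce them over that window. Day length uses a
NOAA-style solar-declination approximation (tested against an independent
oracle to 0.1 h).

What the generator does *not* emulate: interannual autocorrelation and
ENSO-like regimes, rainfall–radiation–temperature cross-correlations, heat
and frost extremes, and trends. Passing tests therefore demonstrate correct
behaviour under stationary, first-order-realistic climates — not
performance against historical records. Each synthetic year is sown fresh
(soil water and N reset at sowing); environments slice a two-season weather
window so late sowings can mature past 31 December.

## 5. Downstream analysis choices

* **Classification**: *null* requires μ\* = 0 in every environment (the
  placeholder contract); *low* is mean μ\* ≤ 0.02 t/ha (boundary inclusive);
  *impactful* above. The threshold is a config value.
* **Clustering**: Ward linkage (`ward.D2`, i.e. Ward on Euclidean
  distances) on the trait × output matrix of mean standardized impacts,
  with each output column z-scored so no output dominates by scale. The
  flat cut defaults to k = 3 groups, exposed in the configuration.
* **η² decomposition**: the additive model impact ~ site + sowing + CO~2~ +
  nitrogen with no interactions, on a balanced grid (enforced with an
  error — sequential sums of squares are only order-free under balance,
  which the tests assert by permuting term order). Year-to-year climate and
  all interactions are pooled into the residual share; degenerate (constant)
  impact vectors return all-zero shares with a flag instead of 0/0.
  Single-level factors (e.g. one sowing date in the desk grid) contribute a
  zero share.
* **Drought environment types**: the reference typology's thresholds are
  not published, so the defaults are: mean stress < 0.2 in both the
  vegetative and grain-fill windows → ET1 ("low"); ≥ 0.5 in both → ET4
  ("severe"); otherwise ET3 ("mild-early") when stress is concentrated
  before flowering and relieved later, ET2 ("mild-late") when it builds
  during grain fill. Both thresholds are configurable.
* **Stress regressions**: per-type ordinary least squares of standardized
  yield impact on the seasonal stress index, with Pearson r; types with
  fewer than 3 environments or a constant stress index are skipped.

## 6. Scale presets, seeds and caching

The `"paper"` preset carries the full study conditions — 90 factors,
6 levels, r = 100 (9 100 virtual genotypes), 4 sites × 125 years × 3 sowing
dates × 3 N levels × 2 CO~2~ levels (9 000 environments), 81.9 million crop
simulations — and is used for planning (`plan_run()`) rather than execution
on a single machine.

The `"desk"` preset is the packaged experiment the tests and examples run
end-to-end: 20 factors (16 active traits + 4 inert placeholders, so the
null/low/impactful partition is exercised), r = 20 (420 genotypes), and
2 sites (Yanco, Merredin — a wetter heavy soil and a dry shallow one) ×
5 synthetic years × 1 sowing × 2 N levels × 2 CO~2~ levels = 40
environments, i.e. 16 800 simulations. Two CO~2~ levels are included so the
CO~2~-response contrast is computable within the preset; the grid stays
balanced for the η² stage. These sizes were chosen once as the smallest
grid that exercises every downstream stage with meaningful contrasts.

All randomness flows from one master seed through `child_seed()` (a Lehmer
step offset by the stage index, kept below 2³¹): design construction and
each site's weather get distinct, reproducible child seeds, and reruns are
bit-identical. Pipeline stages write CSV artifacts with md5 checksums in a
manifest; a rerun with an identical configuration reuses intact artifacts,
recomputes anything missing or corrupted, and a changed configuration
invalidates the cache wholesale. Environments are independent, so the
simulation stage may be parallelised over them without changing results.

## 7. Known limitations

* Surrogate magnitudes: absolute μ\* values are not comparable to a full
  crop model's; rankings and interaction patterns are the meaningful output.
* The nitrogen model is a single mineral pool with critical-dilution
  stress; grain protein is a simple N-transfer bookkeeping, not a
  remobilisation mechanism.
* The weather generator's fidelity limits (section 4) propagate to every
  downstream statistic; in particular drought-type frequencies reflect the
  synthetic climate, not any historical site.
* One plant density, no tillering: `grains_per_gram_stem` absorbs all
  grain-set plasticity.
* Very wide ranges (e.g. ±50 %) can push the phenology and senescence
  behaviour outside the surrogate's sensible regime; the packaged rules
  target the ±20 % screen.
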