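---
title: "Methods: dietary tin exposure and organotin risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary tin exposure and organotin risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tindiet)
```

## The assessment problem

Tin reaches the diet through two routes with very different toxicity:
inorganic tin (mostly from can linings and soil contact), which is poorly
absorbed and tolerated at hundreds of µg/kg bw/day, and organotin
compounds (TBT, DBT, TPT, DOT), whose tolerable daily intake is three
orders of magnitude lower. Routine surveillance measures only *total* tin,
so the package implements both a conventional total-tin hazard screen and
two ways of reasoning about the unmeasured organotin share: a fixed
literature fraction, and a reverse calculation asking how small that share
would have to be before highly exposed consumers hit the organotin TDI.

The packaged inputs are summary statistics of a provincial surveillance
programme: per-food-type censored concentration summaries (25 types,
2,014 samples) and per-age-group consumption quantiles with body weights
(19.9, 33.7, 52.3, 62.1, 60.4 kg for the five study groups; 57 kg for the
whole population).

## Deterministic model

For a food type with concentration $C_v$ (mg/kg), daily consumption $CR$
(g/day) and body weight $BW$ (kg),

$$\mathrm{EDI} = \frac{C_v \times CR}{BW} \quad [\mu g/kg\,bw/day],$$

since mg/kg equals µg/g no unit factor is needed. Hazard quotients divide
by a reference dose, $HQ_i = \mathrm{EDI}_i / \mathrm{RfD}$, and the total
hazard quotient is their sum over food items; THQ > 1 flags concern. The
chronic-duration oral benchmark for (inorganic) tin, 300 µg/kg bw/day, is
applied conservatively to total tin.

Four screening scenarios cross the P50/P95 of consumption with the P50/P95
of concentration (A = P50×P50, B = P95×P50, C = P50×P95, D = P95×P95).
Quantile inputs come from the printed tables when fixtures are used, or
from `empirical_quantile()` on sample-level data — both paths share the
same grid code. Items with a printed median consumption of zero contribute
exactly zero in P50-consumption scenarios; no imputation is attempted.

Two wrinkles in the source tables are handled explicitly rather than
silently:

* **Wet vs dry weight.** Concentrations are reported on a dry-weight basis
  while the intake formula is stated on a wet-weight basis, with no
  conversion factor given. The package applies an identity conversion and
  flags the issue here; all reproduced values are consistent with that
  reading.
* **An inverted quantile pair.** The published dark-tea consumption row
  has P50 > P95 for two age groups, and the published exposure grid uses
  those numbers verbatim. `load_consumption_quantiles()` therefore rejects
  inverted rows by default (`on_inverted = "error"`), but the fixture
  accessor `zj_consumption()` loads with `"keep"` so the published grid is
  mirrored exactly; `"swap"` is available when order-valid quantiles are
  required (e.g. for monotonicity checks).

Recomputing the full published grid from the printed fixtures reproduces
the anchor cells and all totals closely, but not every cell: the printed
concentration percentiles are rounded to two decimals, and multiplying a
rounded 0.00–0.03 mg/kg by a few hundred g/day amplifies the rounding far
beyond the displayed precision. The test suite asserts a 2%/0.01 µg/kg
bw/day band over all 500 cells and reports the non-conforming cells; that
test documents the limitation and is expected to fail against the printed
inputs.

## Organotin screening and the reverse statistic

The screening model multiplies total-tin intake by an assumed organotin
fraction (default 0.0583, the lowest documented organotin share of total
tin in aquatic organisms) and compares it with the organotin TDI expressed
as tin, 0.10 µg-Sn/kg bw/day. The published screening table, however, is
only reproduced when the fraction is 1 — its intake rows are total-tin
values set against the organotin TDI. `organotin_scenario_assessment()`
therefore defaults to the formula as written (fraction 0.0583) and offers
`reproduce_table4 = TRUE` for the published convention; the pipeline and
the percentile-at-TDI table expose the same choice.

The reverse statistic inverts the question. Writing $Q_{1-q}$ for the
simulated exposure level that a fraction $q$ of the population exceeds,

$$p_{\min} = 100 \times \frac{\mathrm{TDI}}{Q_{1-q}} \quad [\%],$$

capped at 100. The conservatism parameter is described in the source as
"P0.5, the 0.5th percentile of the simulated exposure distribution", but
read literally (the *lower* 0.5th percentile) the published category
values are unreachable — they correspond to exposure levels at or above
the deterministic P95×P95 sums — and the published category ordering
inverts in the lower tail, where every concentration sits at LOD/2 and
fruit consumption dominates vegetables. Read as an *exceedance* point (the
upper 99.5th quantile, i.e. the most exposed 0.5%), both the magnitudes
and the ordering (canned < aquatic < vegetables < fruits < tea) are
recovered. The package adopts the exceedance reading; `q` remains a
parameter for probing other conservatism levels.

## Monte Carlo design

Each iteration resamples, per food type, one concentration uniformly with
replacement from the observed (or synthetic) sample values — non-detects
entering at LOD/2, consistent with the substitution rule — and one intake
from the respondent records, then sums `conc × intake / bw` over types.
Category draws are accumulated within the same iteration, so the
total-diet draw dominates every category draw and the total-diet
$p_{\min}$ can never exceed a category's. Defaults: 10,000 iterations,
whole-population body weight 57 kg (per-age weights for age-stratified
runs), all constants overridable.

No analytic form is assumed for the exposure distribution, so confidence
intervals are percentile intervals (2.5th/97.5th) over 200 independent
replicate simulations seeded `seed + 1, …, seed + 200`; the interval is
widened to contain the base-seed point estimate in the rare case a
percentile interval from independent replicates does not. The replicate
count trades runtime for CI stability; the tests verify the expected
$\sqrt{n}$ narrowing. Everything is deterministic given `(seed, config)`.

## The synthetic-data generator

The raw laboratory and survey records are unavailable by design, so the
generator emulates them from the printed summaries.

**Concentrations.** Each food type is a three-part mixture: a point mass
of non-detects at LOD/2 with mass $1 - d$ where $d$ is the printed
detection rate; a lognormal body for detected values; and a single spike
at the printed maximum with mass $\min(1/n, 0.02)$ — one expected sample
at the study size, capped so the spike stays above the matched 95th
percentile. This is the most parsimonious family that matches the printed
skew (means far above medians, maxima far above P95). The lognormal
parameters solve the mixture's P50 and P95 against the printed targets;
when at least half the samples are censored the median is pinned at LOD/2
by the point mass and cannot be matched (the printed medians of two such
rows are display artifacts — the source text itself describes the fish
median as near zero), so only P95 is matched and the log-sd defaults to 1.
Printed quantiles of 0.00 are treated as display-censored and clamped up
to LOD/2 rather than rejected.

**Consumption.** Each (type, age) cell is zero-inflated lognormal. With a
positive median: no zero mass, `log_mu = log(p50)`,
`log_sigma = log(p95/p50) / 1.6449` (1.6449 is the standard-normal 0.95
quantile). With a zero median but positive P95: zero probability 0.6 —
any value above 0.5 keeps the mixture median at zero, and 0.6 is the
minimal-assumption choice, configurable via `zero_prob_default` — with the
lognormal solved so the mixture P95 matches (log-sd default 0.5). A fully
zero cell generates exact zeros.

**Generation.** Counts are deterministic: exactly `round(n × d)` detected
samples and `round(n × zero_prob)` zero intakes, so printed detection
counts are reproduced exactly at the study sizes. Values are placed by
stratified inversion of the mixture quantile function at plotting
positions and shuffled under the seed — the sample *is* the calibrated
distribution up to discretisation, which keeps the loop-closure property
(generate → summarise recovers the printed P50/P95) tight at small study
sizes where i.i.d. draws would be noisy. Three numerical safeguards:
detected values are floored at the LOD (a detected value below the
detection limit is physically inconsistent) and capped at the observed
maximum; and the order statistics flanking the matched quantile positions
are adjusted so the empirical type-7 quantile hits the target exactly —
with 20–30 detected values, linear interpolation between stratified grid
points otherwise overshoots convex upper quantiles by more than 5%.

**What the generator does not emulate.** Within-respondent correlation
across food types (records are independent per type), between-region and
seasonal variation, measurement error, and any joint structure between
concentration and consumption. Passing tests therefore demonstrate that
the pipeline's statistics are correct for data *shaped like* the printed
summaries, not that they reproduce population-level results that depend on
the unpublished raw data — the published percentile-at-TDI values and
exact conversion minima are explicitly out of reach, and only structural
properties (orderings, closed-form recovery, loop closure) are asserted.

## Numerical conventions and degenerate inputs

* Quantiles use linear interpolation between order statistics at position
  $(n-1)q$ (type 7), the common scientific-software default; a
  nearest-rank option exists for sensitivity checks. IQR is Q0.75 − Q0.25
  under the same convention.
* Display rounding follows the publication layouts (concentrations and
  EDIs to 2 decimals, grid THQ to 4, screening THQ to 1); all internal
  computation and all test comparisons use unrounded values.
* Degenerate cases are defined, not errors: equal P50/P95 gives a
  point-mass lognormal (log-sd 0); an empty cell set gives zero exposure
  and THQ 0; an all-zero age/scenario combination reports category shares
  as undefined rather than dividing by zero; a zero exposure quantile in
  the reverse statistic returns the 100% cap with a warning.
* Compliance limits are configuration, not constants: the source narrative
  and its own concentration table disagree about whether canned foods stay
  below 100 mg/kg, so the canned threshold is user-selectable (200
  default, 100 beverage variant) and screening reports against whichever
  is chosen.

## Problem sizes

The test suite calibrates all 25 food types and generates at the study
sample sizes (8–268 per type); forward-simulation oracles use 100,000
samples; Monte Carlo property checks use 10,000 iterations with 20–50
replicates; the reverse-assessment ordering check uses 500 synthetic
respondents per age group. The end-to-end pipeline tests run reduced sizes
(50 respondents per cell, 500 iterations, 5 replicates) chosen to exercise
every stage; the package defaults remain the full study conditions.

## Known limitations

Concentration and consumption data were collected in different periods by
the original programme; the identity wet/dry conversion is an assumption;
the organotin fraction is a single literature value for aquatic organisms
applied as a screen; the zero-inflation fraction for non-consumers is not
identified by the printed tables; and sampling weights, regional strata
and respondent-level correlation are not modelled. The package is a
screening tool: its outputs rank risks and bound them, they do not replace
compound-specific organotin measurement.
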