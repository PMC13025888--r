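# tindiet

Dietary exposure and risk assessment for tin (Sn) in food, built around the
kind of provincial food-surveillance data collected in Zhejiang, China:
left-censored concentration measurements across 25 food types in five
categories (fresh vegetables, tea, fresh aquatic products, fresh fruits,
canned foods), age-stratified consumption quantiles, and the toxicological
benchmarks for total tin and for the far more toxic organotin compounds.

It is intended for food-safety analysts and exposure modellers who need a
tested, reproducible implementation of the screening-level workflow:

* **Censored concentration handling** — non-detects substituted at half the
  limit of detection (LOD 0.004 mg/kg; 0.008 mg/kg for tea), descriptive
  summaries (mean, P50, P95, IQR, min, max) and compliance screening
  against the 200 mg/kg (100 mg/kg beverage) regulatory limits.
* **Deterministic scenario grid** — estimated daily intake
  `EDI = Cv × CR / BW` (µg/kg bw/day) for every food type × age group under
  four scenarios crossing median/high consumption with median/high
  contamination (A = P50×P50, B = P95×P50, C = P50×P95, D = P95×P95), with
  hazard quotients `HQ_i = EDI_i / RfD`, their sum `THQ = Σ HQ_i` against
  the 300 µg/kg bw/day chronic reference dose, and per-category
  contribution shares.
* **Organotin screening** — the aquatic-product scenario grid scaled by an
  assumed organotin fraction of total tin (literature value 5.83%) against
  the organotin TDI of 0.10 µg-Sn/kg bw/day.
* **Probabilistic assessment** — Monte Carlo resampling of concentration ×
  consumption / body weight (10,000 iterations by default, 57 kg
  whole-population body weight), the percentile of the exposure
  distribution at which the TDI is reached, and the *reverse* statistic:
  the minimum percentage of total tin that would need to exist as
  organotin, `p_min = 100 × TDI / Q(1 − q)`, where `Q(1 − q)` is the
  exposure level exceeded by a fraction `q` (default 0.5%) of the simulated
  population. Confidence intervals come from percentile intervals over
  independent seeded replicate simulations.
* **Calibrated synthetic data** — the raw laboratory and survey records
  behind the published summary tables are not public, so the package ships
  a generator that calibrates a censored lognormal mixture (point mass at
  LOD/2, lognormal body, spike at the observed maximum) to each printed
  concentration summary, and a zero-inflated lognormal to each printed
  consumption cell, reproducing detection counts exactly and printed
  P50/P95 to tight tolerance. Every stochastic stage is bit-reproducible
  from its seed.

The printed summary tables of the Zhejiang surveillance (2,014 samples;
consumption and body weights for five age groups) are packaged as CSV
fixtures and load by default.

## Worked example

```r
library(tindiet)

grid <- scenario_exposure_table()   # packaged fixtures by default
grid
#> Deterministic Sn exposure grid: 25 food types x 5 age groups x 4 scenarios
#> Sum of EDIs (ug/kg bw/day) by age group and scenario:
#>  scenario      le6    7_12   13_17   18_59    ge60
#>         A  0.09965  0.1808  0.1253  0.2602  0.1799
#>         B  0.35563  0.4299  0.2997  0.4013  0.3153
#>         C  6.44915  8.1491  5.4984 58.4494  6.3020
#>         D 24.08131 23.8473 16.7168 65.3334 13.9408

hazard_table(grid, tox_constants()$rfd_total_sn)[16:20, ]
#>  age_group scenario  sum_edi        thq exceeds
#>        le6        D 24.08131 0.08027102   FALSE
#>       7_12        D 23.84730 0.07949100   FALSE
#>      13_17        D 16.71680 0.05572266   FALSE
#>      18_59        D 65.33341 0.21777802   FALSE
#>       ge60        D 13.94084 0.04646945   FALSE
```

Even under the worst-case scenario D (high consumption × high
contamination) the total hazard quotient peaks at 0.22 for adults —
dominated by canned fruit — so total-tin exposure stays well below the
safety threshold (THQ < 1) for every age group.

The probabilistic reverse assessment runs on synthetic data calibrated to
the same fixtures:

```r
sd <- simulate_study_data(n_per_age = 500, seed = 1)
reverse_assessment(sd$samples, sd$records,
                   config = mc_config(iterations = 10000, replicates = 50,
                                      seed = 42))
#> Minimum organotin conversion proportion (% of total Sn), top 0.5% exceedance point:
#>          category                p_min
#>  fresh_vegetables    1.88% (1.52-2.19)
#>               tea    46.1% (45.3-46.6)
#>     fresh_aquatic  0.791% (0.727-1.02)
#>      fresh_fruits    10.5% (9.84-10.8)
#>            canned 0.106% (0.106-0.106)
#>        total_diet 0.105% (0.105-0.106)
```

Canned foods and fresh aquatic products need well under 1% of their total
tin to be organotin before highly exposed consumers reach the organotin
TDI, while tea would need roughly half — the same vulnerability ordering
(canned < aquatic < vegetables < fruits < tea) reported for the original
sample-level data.

`run_pipeline(pipeline_config())` executes every stage end to end and
writes publication-layout CSVs plus a YAML manifest; `render_table()`
formats individual stage results the way the published tables print them.

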