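# bsikinetics

Population-level kinetics of C-reactive protein (CRP) and plasma albumin
(PA) in the 30 days before a community-acquired bloodstream infection
(CA-BSI) is diagnosed. Both proteins are acute-phase reactants: CRP rises
and albumin falls when an inflammatory response starts, so their
trajectories in routine hospital laboratory data carry a signal of the
infection's onset days before the diagnostic blood culture is drawn.

The package is for biostatisticians and infection epidemiologists working
with longitudinal laboratory registries. It provides

* **broken-stick regression** (`bsr()`): a continuous two-segment linear
  model with an estimated change-point, fitted to the cohort's daily mean
  concentrations;
* **patient-level bootstrap inference** (`bsr_boot()`, `bsr_group_diff()`,
  `bsr_vs_reference()`): percentile confidence intervals and
  between-group parameter comparisons, resampling patients to respect
  within-patient dependence;
* **registry preprocessing** (`assign_relative_day()`,
  `impute_below_lod()`, `exclude_implausible_pa()`, `select_cohort()`,
  `daily_means()`): relative-day indexing, detection-limit imputation,
  implausible-value exclusion, eligibility filtering and daily aggregation;
* **per-patient slope analysis** (`slope_pairs()`,
  `summarize_slope_patterns()`): early/late window OLS slopes for patients
  with enough specimens in both windows;
* **a synthetic-cohort generator** (`bsi_scenario()`, `simulate_cohort()`,
  `default_paper_scenario()`): cohorts with realistic sampling intensity
  (sparse far from diagnosis, dense at it), right-skewed CRP and normal PA
  noise, detection-limit censoring — so the whole pipeline is testable
  without access to a clinical registry;
* **an end-to-end pipeline** (`run_config()`, `run_analysis()`) writing
  tables, figures and a manifest, plus a thin command line front end in
  `inst/scripts/bsikin.R`.

## The model

Let `y(t)` be the mean biomarker concentration on day `t` relative to the
day the diagnostic blood culture is drawn (day 0; negative days precede
it). The broken stick is

```
E[y | t] = a + b1 * min(t - c, 0) + b2 * max(t - c, 0)
```

with change-point `c`, level `a` at the change-point, and segment slopes
`b1` (before) and `b2` (after). Continuity at `c` is structural. The
change-point is estimated by profiling: for each candidate `c` on a 0.1-day
grid the remaining parameters are ordinary least squares, and the global
SSE minimiser wins (ties break toward the latest change). Confidence
intervals come from a percentile bootstrap that resamples patients, and a
parameter difference between microbial groups (monomicrobial Gram-positive,
monomicrobial Gram-negative, polymicrobial) is significant when the 95%
bootstrap interval of the replicate differences excludes zero.

## Worked example

```r
library(bsikinetics)

scenario <- default_paper_scenario(500)       # reference kinetics, 500 patients
cohort   <- simulate_cohort(scenario, seed = 2026)

m   <- window_measurements(cohort$measurements)
crp <- impute_below_lod(m[m$biomarker == "CRP", ])   # "<10 mg/l" -> uniform 0..9
pa  <- exclude_implausible_pa(m[m$biomarker == "PA", ])
m   <- rbind(crp, pa)

ci <- bsr_boot(m, "CRP", n_reps = 1000, seed = 1)
ci
#> Broken-stick fit with patient-bootstrap CIs (CRP, 494 patients, 1000 replicates, 0 failed)
#>            estimate   2.5%  97.5%
#> c            -3.100 -3.300 -2.700
#> level_at_c   84.989 82.003 88.288
#> slope_pre    -1.556 -1.778 -1.310
#> slope_post   38.575 35.809 43.884
```

The fitted change-point says the cohort's mean CRP course turned 3.1 days
before diagnosis: roughly flat (−1.6 mg/l/day) until then, rising steeply
(about +39 mg/l/day) afterwards. The per-patient view:

```r
sp <- slope_pairs(m, cohort$patients, "CRP")  # >=2 specimens in both windows
sm <- summarize_slope_patterns(sp, "CRP")
#> 299 of 372 slope-pair patients (80.4%) show a late CRP rise
```

`plot(ci$fit)` draws the daily means with the fitted stick and an arrow at
the change-point; `plot(sp)` gives the early-vs-late slope scatter.

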