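# revstab

Revision instability analysis for repeatedly re-estimated burden-of-disease
panels.

Burden-of-disease programmes re-estimate their entire historical time series
with every release cycle, so the published estimate for "deaths attributable
to risk X in year Y" is revised again and again across iterations. revstab
treats those revisions as data for meta-epidemiological assessment: how far
do successive releases move the same number, and is the movement
communicated by the published uncertainty intervals?

The package is for meta-researchers and epidemiologists auditing the
stability of descriptive health estimates (deaths, DALYs) across release
iterations.

## What it computes

For a long-format table of estimates (risk × metric × release iteration ×
calendar year × stratum, optional 95% UI):

* **Alignment** — *index-year series* (each release's estimate for its own
  final year) and *matched-year panels* (every value ever published for one
  calendar year, i.e. the original estimate plus all its revisions).
* **Instability statistics** — for each panel of values $v_1,\dots,v_n$:
  the range-to-mean ratio $\mathrm{R{:}M} = (\max v - \min v)/\bar v$ and
  the coefficient of variation $\mathrm{CV} = s/\bar v$ (sample SD), with
  strict threshold flags: R:M > 1 of concern, > 1.5 extremely high;
  CV > 0.2 high, > 0.5 very high. Group rollups report round-half-up
  integer percentages ("17 of 34 (50%)").
* **UI consistency** — classification of each later-iteration point against
  the earlier iteration's 95% UI (below / within / above, closed interval),
  cell-wise on the finest stratification, with data-driven denominators.
* **Ranking churn** — within-iteration burden ranks over a fixed risk set
  and the longest run of consecutive iterations with unchanged rank.
* **Synthetic revision process** — a seeded lognormal generator
  $V_{r,i,y} = A_r e^{g_r (y-y_0)} e^{\delta_{r,i}} e^{\varepsilon_{r,i,y}}$
  with closed-form calibration targets
  (`theoretical_cv()`, `theoretical_ui_within()`), so the whole pipeline is
  testable without any external download.

## Worked example

The package ships a small illustrative fixture (four dietary/activity risks,
four release iterations) under `inst/extdata/`.

```r
library(revstab)

est  <- system.file("extdata", "example_estimates.csv", package = "revstab")
map  <- system.file("extdata", "example_map.csv",       package = "revstab")
hier <- system.file("extdata", "example_hierarchy.csv", package = "revstab")

tab <- read_estimates_csv(est) |>
  harmonize(read_harmonization_map(map), read_risk_hierarchy(hier)) |>
  filter_analysis_set()

idx <- build_index_year_series(
  tab, default_iteration_index_map(c(2015L, 2017L, 2019L, 2021L)))
as.data.frame(summarize_panels(idx, "index_year")[, c("risk_id", "n", "min", "max",
                                                      "rm", "cv", "rm_flag", "cv_flag")])
#>                 risk_id n    min     max        rm        cv rm_flag   cv_flag
#> 1   diet_processed_meat 4 137000  841000 1.7721838 0.7710807 extreme very_high
#> 2         diet_red_meat 4  25000  896000 3.2530345 1.5677064 extreme very_high
#> 3              diet_ssb 4  26000  300000 1.8864028 0.7830676 extreme very_high
#> 4 low_physical_activity 4 658000 1650000 0.8841355 0.3992260     low      high
```

Across the four iterations, the red-meat estimate spans 25,000–896,000
deaths — a range 3.25 times its mean, far past the 1.5 "extremely high"
cutoff — while low physical activity stays below the concern threshold
(R:M 0.88). The CV flags tell the same story on the SD scale.

UI consistency of the 2021 revision against the 2019 intervals:

```r
cov <- summarize_coverage(
  compare_iterations(build_time_series_panels(tab), 2019, 2021))
as.data.frame(cov[cov$risk_id == "(all)", c("n_total", "n_below", "n_within",
                                            "n_above", "pct_outside")])
#>   n_total n_below n_within n_above pct_outside
#> 1      12       0        6       6          50
```

Half of the revised points fall outside the intervals the previous release
published for the same cells — revisions larger than the stated uncertainty.
`run_pipeline()` (or the `inst/scripts/revstab.R` command-line wrapper) runs
all stages at once and writes the report bundle — per-panel summaries, the
matched-year R:M matrix, group rollups, coverage tables, rank trajectories,
exclusion ledgers — as tidy CSVs with a checksummed manifest.

For full-scale analyses of real release extracts (which must be downloaded
by the user), `inst/scripts/reproduce_gbd.R` accepts canonical-schema CSVs
and re-emits the same bundle.

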