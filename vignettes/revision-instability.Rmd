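---
title: "Quantifying revision instability in repeatedly re-estimated burden panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying revision instability in repeatedly re-estimated burden panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revstab)
```

## The problem

Global burden-of-disease programmes re-estimate their entire historical time
series with every release cycle: the 2019 release publishes estimates for
1990–2019, the 2021 release re-publishes 1990–2021, and so on. The number
printed for "deaths attributable to risk X in 2015" therefore exists in many
versions, one per release iteration, and those versions can differ by large
factors even though they describe the same quantity in the same year. Since
point estimates — not their uncertainty intervals — usually drive policy,
the size of these retrospective revisions is itself an empirical measure of
how far the estimates can be trusted.

revstab operationalizes that measurement. It takes a long-format table of
published estimates (risk × metric × release iteration × calendar year ×
stratum, with optional 95% uncertainty intervals), aligns it two ways, and
quantifies instability:

* **Index-year series** — each iteration's estimate for its own final
  ("index") year: the 2010 release's number for 2010, the 2013 release's for
  2013, and so on. Instability here mixes genuine temporal change with
  revision effects.
* **Matched-year panels** — every value ever published for one fixed
  calendar year. Here the *only* thing that varies is the release iteration,
  so spread across a panel is revision instability by construction.

## The statistics

For a panel of values $v_1, \dots, v_n$ ($n \ge 2$, values nonnegative):

* **Range-to-mean ratio** $\mathrm{R{:}M} = (\max v - \min v) / \bar v$.
  Dimensionless and scale-invariant; 0 for a constant panel; for two values
  $a \le b$ it reduces to $2(b-a)/(a+b)$, so it is bounded by 2 for pairs.
* **Coefficient of variation** $\mathrm{CV} = s / \bar v$ with $s$ the
  sample standard deviation ($n-1$ denominator).

Interpretation thresholds use strict inequalities throughout: R:M > 1 is *of
concern* (the range of published values exceeds their mean), R:M > 1.5 is
*extremely high*; CV > 0.2 is *high* and CV > 0.5 *very high*. A value
exactly at a cutoff stays in the lower category. All four cutoffs are
configuration, not constants (`default_thresholds()`).

Group rollups count panels above the cutoffs and report proportions as
round-half-up integer percentages (the "17 of 34 (50%)" reporting style);
`round_half_up()` exists because base R's banker's rounding prints 50.5% as
50%.

Two open choices are worth stating. First, the denominator of R:M: we use
the arithmetic mean (with the median selectable via `center = "median"`);
published per-risk rows of the form "median 73, range 25–896, ratio 3.8" are
arithmetically consistent only with a mean denominator, and the test suite
carries that inverse-consistency check. Second, the CV's SD denominator is
the sample convention $n-1$, selectable to $n$, because at panel sizes 2–8
the choice is material.

## Uncertainty-interval consistency

A complementary question: when a release revises a value, does the new point
at least fall inside the 95% uncertainty interval the *previous* release
published for that same cell? `compare_iterations()` joins two iterations
cell-wise on the finest available stratification (risk × metric × sex ×
location × cause group × year) and classifies each later point as below,
within, or above the earlier UI. Containment is closed-interval: boundary
equality counts as within, because "outside" is read strictly and ties are
measure-zero on real data. Cells present on only one side, or lacking a UI,
are excluded and ledgered — denominators are data-driven, never imputed.

## Ranking churn

`rank_trajectories()` ranks a fixed, user-specified risk set within each
iteration (rank 1 = largest burden, ties broken lexicographically for
determinism) and summarizes each risk's trajectory by the longest run of
consecutive iterations with an unchanged rank and the range of ranks
visited. Iterations missing any member of the set are dropped from the
ranking and ledgered rather than ranked on a shrunken set: rank numbers are
only comparable when the candidate set is identical.

## The synthetic revision process

Real release extracts cannot be bundled, so the package ships a generative
stand-in that makes every pipeline stage testable with known truth. The
value iteration $i$ publishes for risk $r$ in year $y$ is

$$V_{r,i,y} = A_r \, e^{g_r (y - y_0)} \, e^{\delta_{r,i}} \, e^{\varepsilon_{r,i,y}},$$

with $A_r$ a log-uniform baseline, $g_r$ a smooth true trend,
$\delta_{r,i} \sim N(0, \tau^2)$ a systematic per-iteration revision shift
(independent per iteration, or a random walk of such increments in
`random_walk` mode), and $\varepsilon \sim N(0, \sigma^2)$ iid observation
noise. Published intervals are $V e^{\pm z s_{ui}}$. The model is
multiplicative because burden estimates are positive and observed revisions
are fold-change-like; it exists purely to make the pipeline testable, not as
a model of how any real estimation machinery behaves.

Two closed forms calibrate the pipeline end to end:

* matched-year values for one (risk, year) are lognormal with log-SD
  $\sqrt{\tau^2 + \sigma^2}$, so their population CV is
  $\sqrt{e^{\tau^2+\sigma^2} - 1}$ (`theoretical_cv()`);
* the log-difference between two independent iterations' points has SD
  $\sqrt{2(\tau^2+\sigma^2)}$, so the probability that a later point falls
  inside an earlier UI is
  $2\Phi\!\big(z s_{ui} / \sqrt{2(\tau^2+\sigma^2)}\big) - 1$
  (`theoretical_ui_within()`); setting $s_{ui} = \sqrt{2(\tau^2+\sigma^2)}$
  makes the nominal level 95% at $z = 1.96$.

Default conditions: eight release cycles (2010, 2013, 2015, 2016, 2017,
2019, 2021, 2023), each estimating 2010 up to its own index year;
$\tau = 0.3$ and $\sigma = 0.1$, i.e. iteration-to-iteration fold changes of
the size seen in volatile behavioral-risk estimates, with observation noise
an order of magnitude smaller in variance; baselines spanning $10^4$–$10^7$
(small individual risks to large aggregates) and true trends up to
±2%/year. One seeded generator drives all draws in a fixed order (risk
baselines, then per-iteration shifts, then per-record noise), so a seed
reproduces the table bit-for-bit, and the full truth ($A_r$, $g_r$,
$\delta_{r,i}$, $\varepsilon$) is returned alongside the records for exact
reconstruction tests.

```{r example}
sim <- simulate_estimates(synthetic_config(n_risks = 20, seed = 42))
tab <- filter_analysis_set(harmonize(sim$table, sim$map, sim$hierarchy))
summ <- summarize_panels(build_matched_year_panels(tab), "matched_year")
median(summ$cv)
theoretical_cv(0.3, 0.1)
```

The empirical median sits somewhat *below* the population CV: panels hold
2–8 values and the sample SD is biased downward at such sizes (the
expectation factor $c_4(n)$ is 0.80 at $n=2$ and 0.97 at $n=8$). The
calibration tests use a ±0.05 band around the closed form to accommodate
exactly this bias; at the default panel-size mix the bias is ≈ 0.04.

What the generator does **not** emulate: correlated revisions across risks
(real methodology changes move whole risk families together), heavy-tailed
or one-off definitional jumps, trends in UI width across iterations, and
hierarchical aggregation constraints (children summing to parents). Passing
calibration tests therefore demonstrate that the *pipeline arithmetic* is
correct under a known process — not that real release data satisfy these
distributional assumptions.

## Numerical and degenerate-input conventions

* Panels with fewer than two values are skipped into a ledger
  (`skipped_panels()`), never summarized as zero.
* An all-zero panel has R:M = CV = 0 by convention (zero range); a zero mean
  with unequal nonnegative values is impossible and asserted.
* A fully degenerate process ($\tau = \sigma = 0$ *and* zero trend) drives
  every statistic to exactly 0 and every UI verdict to "within" through the
  whole pipeline; this is the suite's end-to-end zero test. With a nonzero
  true trend, index-year R:M is legitimately nonzero even at
  $\tau = \sigma = 0$ — that spread is genuine change, not instability —
  which is why the zero test also flattens the trend.
* Harmonization resolves (raw name, iteration)-specific entries before
  any-iteration entries; unmapped names are excluded-with-report, not fatal,
  and never silently dropped.
* Record counts reconcile at every stage:
  input = analyzed + excluded + unmapped, enforced in the run manifest.

## Problem sizes in the test suite

Unit tests run on constructed panels of 2–8 values and crossed fixtures of a
few risks. Calibration tests use 500 risks × 8 iterations (≈ 6,000
matched-year panels) for the CV target and 600 risks (6,000 UI comparisons)
for the coverage target; oracle-equivalence sweeps use 1,000 random vectors.

## Limitations

The package measures instability of *published point estimates* only; it
does not propagate the estimates' own statistical uncertainty into R:M or CV
(large revisions can be compatible with wide intervals), does not model why
revisions happen, and deliberately refuses to impute missing cells, so all
denominators depend on what was actually published. The full-scale analysis
of real release data requires user-acquired extracts; the packaged fixture
and the synthetic generator are the only bundled inputs.
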