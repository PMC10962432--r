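---
title: "Methods: event-aligned moving-median biomarker time-courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-aligned moving-median biomarker time-courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdtrace)
```

## The setting and the core assumption

Each brain-dead organ donor contributes three serum samples at clinically
defined events — admission (DB1), confirmation of brain death after the
second brain-stem test (DB2), and the end of donor management (DB3). The
only time point that is clinically comparable across donors is DB2, so it
is set to t = 0 in every donor; DB1 then sits at a donor-specific negative
time and DB3 at the donor's brain-death duration. No single donor's three
points can define a trajectory, and connecting all donors' points
chronologically would assume *identical* kinetics across donors. The
package makes the weaker assumption that donors follow *qualitatively
similar* trajectories, under which an ensemble of event-aligned samples
carries time-course information that a moving median can extract, provided
the window is wide enough to absorb between-donor variability.

## The moving-median estimator

For one marker, with pooled aligned samples $(t_i, y_i)$ on the
$\ln(y+1)$ scale, the estimator evaluated at grid time $t$ is the median
of all samples inside a window of width $W$ — but with strict segment
separation:

* $t < 0$: only samples with $t_i < 0$ and $|t_i - t| \le W/2$;
* $t = 0$: all samples with $t_i = 0$ (the DB2 class), regardless of $W$;
* $t > 0$: only samples with $t_i > 0$ and $|t_i - t| \le W/2$.

Samples at exactly $t_i = 0$ therefore belong to the $t = 0$ estimate and
never to a pre- or post-event window. This matters scientifically:
management before brain death and donor management after it are different
clinical regimes, and the estimator guarantees that perturbing one side
cannot move the other (a property the test suite checks exactly, on 100
random fixtures per direction).

Numerical conventions: window boundaries are closed ($\le W/2$);
even-count windows return the midpoint of the two central order
statistics; the evaluation grid always contains $t = 0$ exactly.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_width` | 20 | h | wide enough that adjacent windows share most donors, absorbing donor-specific kinetics |
| `pre_extent` / `post_extent` | 20 / 40 | h | the admission-lead and management horizons the sampling design covers |
| `grid_step` | 1 | h | fixed grid so time courses from different runs are directly comparable |
| `min_window_n` | 3 | samples | below three samples a "median" is one or two donors; such grid points are reported as undefined rather than shown as trend |
| `post_window` | `"centered"` | — | symmetric with the pre-event definition; `"trailing"` ($t-W \le t_i \le t$) is provided because a one-sided reading of the post-event window is also defensible |

The t = 0 estimate is exempt from `min_window_n` because the DB2 class is
a designed, complete stratum (every donor has one), not a window.

### Trend classification

`classify_trend()` reduces each reconstructed curve to four segment
summaries: the mean of defined pre-event medians $\bar m_{pre}$, the value
at zero $m_0$, and the means of the early and late halves of the defined
post-event medians ($\bar m_{early}$, $\bar m_{late}$; the split is at the
median defined post-event grid time, so sparse tails do not starve one
half). Differences are compared against a threshold
$\tau = \text{rel\_threshold} \times \text{level scale}$, where the level
scale is the mean absolute defined median of that marker. The threshold is
*relative* (default 0.15, i.e. 15 % of the marker's overall level on the
ln scale) rather than absolute: markers live at different magnitudes, and
an absolute ln-unit threshold would sit inside the sampling noise of the
segment summaries for a cohort of two dozen donors while being
over-conservative for high-baseline markers. The decision table, applied
in order:

1. $\bar m_{late} - \bar m_{pre} < -\tau$ and $m_0 - \bar m_{pre} < -\tau$
   → **declining** (the fall is already under way at the event);
2. $\bar m_{late} - \bar m_{pre} < -\tau$ otherwise →
   **plateau_then_decline** (level through the event, falling later);
3. $m_0 - \bar m_{pre} > \tau$ and $\bar m_{early} - \bar m_{pre} > \tau$
   and $\bar m_{late} - \bar m_{pre} > \tau$ → **step_increase**
   (a sustained jump at the event);
4. otherwise → **constant_elevated**.

The fallback label is deliberately the constant one: a marker is called
changing only on positive evidence exceeding the threshold.

## Outlier handling

The outlier step protects the pooled medians from donors whose serum panel
is globally aberrant (haemolysis, undocumented infection, assay failure).
The named procedure in this literature — robust regression followed by
outlier removal (ROUT) — fits a model, estimates a robust residual scale,
and flags false-discovery-controlled outliers. With only three samples per
donor there is no per-donor regression to fit, so the package applies the
same machinery cross-sectionally: within each marker and each time-point
class (DB1/DB2/DB3 — the only strata where donors are exchangeable), the
location is the median; the robust scale is the 68.27th percentile of
absolute residuals with an $n/(n-1)$ small-sample correction (the robust
standard deviation of the residuals, RSDR); residuals become t-like
statistics with $n-1$ degrees of freedom; and the marker's p values are
Benjamini–Hochberg adjusted with discoveries at rate $Q$ (default 1 %, the
conventional ROUT default; $Q = 0$ admits none). A simple MAD rule
($|r| > k \cdot \text{MAD}$, $k = 3.5$) is available for sensitivity
analysis; it is shift-equivariant by construction.

A donor is excluded when at least 4 of the 5 measured molecules have at
least one flagged sample. "At least 4 results out of the five measured
serum molecules" is read as counting *markers*, because the count is tied
to molecules; counting individual flagged *samples* instead is available
behind `count_by = "sample"`. Markers observed on fewer than 5 donors are
not assessed (flagging from so few exchangeable values would be
meaningless), and all-identical classes yield no flags with a warning
rather than an error.

## Cohort construction

Eligibility requires consent, a full three-sample set, intracranial
haemorrhage as the cause of death, a documented brain-death duration, and
no documented systemic source of inflammation (represented as a boolean
flag; the package does not parse clinical notes). The 10–30 h study window
is split into four 5-h blocks with half-open intervals $[lo, hi)$ — the
printed block labels overlap at their endpoints, and half-open intervals
are the unique convention that assigns every duration exactly once.
Durations below 10 h and at or above 30 h form the short and long
extremes, which bypass balancing: all their eligible donors are included,
since they exist to extend the observable timeline, not to be compared.

Within each 5-h block, `group_size` donors (default 5) are selected to
minimise an imbalance score: the sum over covariates (age, BMI, sex,
hypertension, diabetes by default) of the absolute standardized difference
between the group mean and a pooled target. The target centre for
continuous covariates is the pooled *median* of the core-block candidates
— a mean target is exploitable by a single extreme candidate, which drags
the target toward itself and makes its own inclusion score-optimal,
the opposite of what matching is for. Blocks with at most 8 candidates are
solved exactly by enumeration; larger blocks by a seeded greedy swap
descent that restarts its scan after every improving swap. Candidates are
sorted by donor id before optimisation, so the selection is invariant to
input row order at a fixed seed. The original study does not state its
matching algorithm; this procedure is a reproducible, auditable stand-in,
and the balance it achieves is always reported (one-way fixed-effects
ANOVA per continuous covariate across the core blocks).

## What the synthetic generator emulates — and what it does not

The generator produces the statistical structure the analysis assumes:

* three samples per donor per marker, anchored at DB2, with the DB1 lead
  drawn uniformly from 2–20 h before the event and DB3 at the brain-death
  duration (uniform 10–30 h by default, or an explicit stratified design
  via `simulate_study_panel()`: 2 short + 4×5 core + 5 long = 27 donors);
* five markers with the four qualitative shapes the classifier must
  distinguish — TNF-α declining (−0.05 ln-units/h), IL-6 plateau until
  10 h post-event then declining (−0.1 ln-units/h), C5a and NSE constant
  (baselines 5.0 and 4.0), GFAP stepping by +2.0 ln-units at t = 0 from a
  1.5 baseline (kept well above zero so raw concentrations remain positive
  under noise);
* additive Gaussian noise on the ln(y+1) scale (SD 0.3), i.e.
  multiplicative on the raw scale, matching the scale on which the
  analysis operates;
* a per-donor random intercept (SD 0.3) *shared across markers*, so that
  injected outlier donors are plausible whole-donor anomalies — the object
  the donor-level exclusion rule is aimed at;
* duplicate raw readings split symmetrically around the true mean with a
  10 % coefficient of variation (typical intra-assay ELISA variability);
  the split preserves the mean exactly, so duplicate averaging is unbiased
  by construction;
* a 6/27 share of donors whose DB1 clock time is flagged as imputed from
  transport records (a provenance flag, not a missing value — the analysis
  carries the flag through);
* donor age anticorrelated with brain-death duration (target Pearson
  r = −0.57, the value implied by a reported R² of 0.33), reflecting
  clinical decision-making about older donors.

Concentrations are in arbitrary units; ln(y+1) is unit-dependent, and no
physical units are claimed. The generator does **not** model release or
clearance kinetics, treatment effects of donor management, recipient
outcomes, assay plate effects or standard curves, or donor-specific kinetic
shapes beyond the shared-shape-plus-intercept structure. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
structure it assumes under realistic noise — not that real donor serum
follows these curves.

## Problem sizes and determinism

All simulation-based checks run at the study's own scale: cohorts of 24–27
donors, five markers, three samples each; recovery properties use 100
replicate cohorts, oracle comparisons 200 random fixtures, and the
exhaustive-search check enumerates blocks of ≤ 8 candidates. Every random
draw flows through a fixed seed; `simulate_donor_panel()` restores the
caller's RNG state, and pipeline stages derive their seeds from the root
seed (simulation: seed; stratified durations: seed + 1; cohort selection:
seed + 2), so a rerun of `run_pipeline()` with the same configuration and
seed reproduces every CSV byte-identically.

## Known limitations

* With three samples per donor, the moving median inherits the sampling
  design: the far post-event tail (beyond ~30 h) is supported by few
  donors and is frequently undefined at the default `min_window_n`.
* The trend classifier is a deterministic decision table, not a test; it
  reports no uncertainty, and near-threshold cohorts can flip labels
  between replicates. Its recovery rate under the default noise model is
  measured, not assumed (see `scripts/acceptance.R`).
* The balanced-selection optimiser is a stand-in for an unstated matching
  procedure; different reasonable scores select different cohorts, which
  is why the selection is seeded, audited, and reported with balance
  statistics rather than presented as canonical.
* Exact reproduction of any real-data curve is impossible without the
  original biobank samples; the package's claims are about the method's
  behaviour under its stated assumptions.
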