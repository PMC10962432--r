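# bdtrace

Event-aligned serum biomarker time-courses in brain-dead organ donors.

## The problem

Organs for transplantation are most often donated after brain death (DBD).
The consensus view has been that brain death unleashes a progressively
proinflammatory "cytokine storm", motivating rapid organ recovery. Testing
that view directly is hard: each donor yields only three serum samples, each
drawn at a *clinical* event rather than at a scheduled time — hospital
admission (DB1), confirmation of brain death after the second brain-stem
test (DB2), and the end of donor management just before organ recovery
(DB3) — and the duration of brain death (BD) differs between donors.

`bdtrace` implements a "post hoc cohort" workflow that turns such sparse,
irregularly sampled panels into one global time course per marker:

1. **Cohort construction** — apply inclusion/exclusion criteria (consent,
   full three-sample set, intracranial haemorrhage as cause of death,
   documented BD duration, no systemic source of inflammation), stratify
   the 10–30 h study window into four 5-h BD-duration blocks, and select a
   covariate-balanced group from each block (plus all donors at the <10 h
   and >30 h extremes), with one-way ANOVA balance diagnostics.
2. **Preprocessing** — average duplicate ELISA readings on the raw scale,
   transform to `ln(y+1)`, flag outliers per marker with a ROUT-style
   robust procedure (median location per time-point class, robust scale
   from the 68.27th percentile of absolute residuals, FDR-controlled
   discoveries at rate Q), and exclude donors that are outliers in at
   least 4 of the 5 measured molecules.
3. **Time-course reconstruction** — set DB2 as t = 0 in every donor and
   smooth the pooled samples with an asymmetric moving median: for t < 0
   the median of all pre-event samples in a 20-h window centred on t, for
   t > 0 the same using only post-event samples, and at t = 0 the median
   of all DB2 samples. For each marker the reconstructed curve is
   classified as `declining`, `plateau_then_decline`, `constant_elevated`,
   or `step_increase`.

Because the original biobank data are not publicly downloadable, the
package ships a first-class synthetic-data module that simulates donor
panels with the study's statistical structure (three anchored samples per
donor, donor random intercepts, multiplicative noise, duplicate readings,
imputed DB1 admission times, injectable whole-donor outliers), so every
stage is testable end to end.

## The estimator

For marker m with pooled aligned samples \((t_i, y_i)\) on the
\(\ln(y+1)\) scale, the moving-median time course with window width
\(W = 20\) h is

```
M_m(t) = median{ y_i : t_i < 0, |t_i − t| ≤ W/2 }   for t < 0
M_m(0) = median{ y_i : t_i = 0 }
M_m(t) = median{ y_i : t_i > 0, |t_i − t| ≤ W/2 }   for t > 0
```

evaluated on a 1-h grid from −20 h to +40 h; grid points supported by
fewer than `min_window_n = 3` samples are reported as undefined. Strict
pre/post separation means management before brain death can never leak
into the post-event trajectory, and vice versa.

## Worked example

```r
library(bdtrace)

panel <- simulate_study_panel(seed = 3, n_outlier_donors = 3)  # 27 donors
eligible <- apply_inclusion_exclusion(panel$donors, panel$samples)$eligible
cohort <- select_balanced(eligible, seed = 5)

samples <- preprocess_samples(
  panel$samples[panel$samples$donor_id %in% cohort$selected_donor_ids, ])
report <- outlier_report(samples, threshold = 4)
report
#> Outlier report (rout method): 15 flagged (donor, marker) pairs; 3 donor(s)
#> excluded at threshold 4 (marker counting)
#> Excluded: D022, D026, D027

aligned <- align_to_bd(exclude_outlier_donors(samples, report), panel$donors)
fit <- bd_timecourse(aligned)
summary(fit)
#> Moving-median time-course summary (ln(y+1) scale)
#>  marker pre_mean value_at_zero post_mean                trend
#>   TNF-a    3.425         3.024     2.011            declining
#>    IL-6    4.199         4.082     2.951 plateau_then_decline
#>     C5a    5.048         5.070     5.037    constant_elevated
#>     NSE    4.044         4.096     3.893    constant_elevated
#>    GFAP    1.514         3.427     3.701        step_increase
```

The three injected whole-donor outliers are removed (27 → 24 donors), and
the reconstructed trends read exactly as the simulated biology: TNF-α
declines from admission onward, IL-6 plateaus around confirmation of brain
death and then declines, C5a and NSE stay elevated throughout, and GFAP
steps up at t = 0 — no progressive proinflammatory rise.
`plot(fit, marker = "GFAP")` draws the individual donor trajectories
(panel A) and the moving-median curve (panel B); `run_pipeline(outdir)`
drives all stages from one seed and writes CSVs, figures, trend labels and
a reproducibility manifest.

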