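---
title: "Linking hip PROMs: scoring, equating and validation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking hip PROMs: scoring, equating and validation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipcrosswalk)
```

This vignette documents the models and procedures behind `hipcrosswalk`,
the choices made where the field leaves the details open, and what the
bundled synthetic cohort can and cannot tell you about real data.

## The problem

Patient-reported outcome measures (PROMs) after total hip arthroplasty
(THA) have shifted over the decades from the (modified) Harris Hip Score
to the HOOS family. A *crosswalk* converts a score on one instrument to
the equivalent score on another, so that historical mHHS collections can
be benchmarked against registry HOOS data. The package scores both
instruments from raw item responses ("patient-derived", PD, scores),
links them by observed-score equating, and quantifies how faithful the
conversion is ("crosswalk-derived", CWD, versus PD).

## Instruments and scoring rules

**mHHS.** The patient-reported part of the Harris Hip Score: one pain
item (up to 44 points), three gait items (limp, support, walking
distance; up to 33), and the daily-activity items stairs, shoes/socks and
sitting (up to 13). The public-transport item (1 point) is retained in
the rubric but excluded from the total, giving a 0–90 range (the full
patient-reported rubric would reach 91). Item weights are the standard
Harris values, shipped as an editable CSV (`inst/extdata/mhhs_rubric.csv`)
and checked at load time against the instrument's published domain totals
(44 / 33 / 14 / 13 / 90 / 91) — so an edited rubric that breaks those
totals is rejected rather than silently mis-scored. Because the weights
are unequal, a visit with **any** missing retained item gets a missing
mHHS: imputing a 4-point item where an 11-point item is missing would not
be defensible.

**HOOS.** Forty items in five subscales (pain 10, symptoms 5, activities
of daily living 17, sport 4, quality of life 4), each item coded 0 (best)
to 4 (worst). A subscale is transformed to
`100 − mean(answered codes)/4 × 100`, so 100 is best. A subscale is
computed when at least half of its items are answered (the instrument's
customary missing rule, using the mean of the answered items); otherwise
it is flagged missing — never zeroed. The *overall* HOOS used for the
crosswalks is the unweighted mean of the five subscale scores. That
aggregation is a documented package choice: the overall 0–100 HOOS is
routinely reported but its construction from the subscales is not
standardised, and the unweighted mean is the simplest defensible reading.
The weighted-mean identity in the MAE report (overall = count-weighted
mean of strata) makes it easy to recompute under another convention.

**HOOS-12.** Scored from a completed HOOS using only 12 designated items
in three 4-item scales (pain, function, quality of life), each on 0–100,
with their unweighted mean as the total. The bundled item mapping
(`inst/extdata/hoos12_items.csv`, see `hoos12_item_map()`) follows the
short form's structure — four pain items, four function items drawn from
the ADL scale, and the full four-item quality-of-life scale — and is
shipped as editable configuration so sites using a different licensed
mapping can substitute theirs. A note on raw subcategory points: the four
pain items span 16 raw severity points; descriptions of the short-form
activity domain as "8 questions (12 points)" are internally inconsistent
(eight 0–4 items cannot total 12), so the package follows the 12-item /
three-scale structure and documents rather than resolves that
inconsistency.

**Subcategory scales.** The pain/activity subcategory analysis compares
instruments on the scales their error tables conventionally use: HOOS and
HOOS-12 pain/activity rescaled to 0–100, mHHS pain raw out of 44 and mHHS
activity (stairs + shoes/socks + sitting) raw out of 13.

## Equating methods

Two linking methods are implemented; both consume a `matched_pair_set` of
PD scores at common patient-visits and produce a `crosswalk_table` over
the **full integer source grid** (0–90 for mHHS, 0–100 for HOOS/HOOS-12),
even where no patient scored — published crosswalk tables cover the whole
range, and so do ours.

**Equipercentile (EQ).** Non-parametric: source and target scores with
equal percentile ranks are equivalent. The package uses mid-percentile
ranks, `P(x) = 100(#{xᵢ<x} + ½#{xᵢ=x})/n`, with *linear continuization*:
between consecutive observed distinct scores the rank function is
interpolated linearly, and the target-side inverse interpolates the same
way. This is the standard observed-score treatment of discrete score
distributions; a discrete rank-matching variant would differ only between
observed scores. Grid points outside the observed source data are mapped
linearly from the outermost observed conversion to the target range
endpoint — bounded instruments forbid open-ended extrapolation, and the
ramp keeps the table monotone and range-safe by construction. No
presmoothing (log-linear or kernel) of the score distributions is
applied; with ~121 pairs the raw distributions are used directly, and
presmoothing is a possible extension.

**Linear regression (LR).** Ordinary least squares of target on source PD
scores (`stats::lm`), with intercept, no weighting by time point. The
line is tabulated on the integer grid and clamped to the target range;
where clamping occurs (for instance a negative intercept at source 0) a
warning is logged, since the published equations themselves leave the
range at the extremes. Slope and intercept are kept at full precision in
`fit_meta` and in the exported table header.

**Rounding.** Crosswalk CSVs carry both an exact column and an integer
column (round half away from zero). All validation uses exact values;
rounding first would add ±0.5 discretisation noise.

**Gate.** Crosswalks are only built when Spearman's ρ between the paired
PD series (average-rank ties) reaches 0.3, the customary minimum for
score linking; below it, construction fails with a typed condition
(`hipcw_gate_failure`) carrying the computed ρ, and the command-line
`build` writes nothing.

## Validation

MAE = mean |CWD − PD| over matched pairs, computed on unrounded CWD
values, overall and per time point (pre-op, 3, 6, 12 months); an empty
stratum is reported absent, not zero. The overall MAE pools all pairs;
because overall = count-weighted mean of the stratum MAEs (asserted in
the tests to 1e-9), readers preferring the average-of-strata convention
can recompute it from the report. The largest |CWD − PD| is reported
together with the source score at which it occurs. Subcategory (pain /
activity) validation uses EQ only: the subcategory scores are coarse
step-like series — mHHS pain takes six values — and a fitted line through
them adds assumptions the data cannot support.

**Power analysis.** `required_sample_size()` finds the smallest *n* at
which the test of ρ = 0 against ρ = `r_min` reaches the target power,
using the bias-corrected Fisher-z approximation
`z_r = atanh(r) + r/(2(n−1))` against the t-based critical correlation.
Sidedness matters: with ρ = 0.3, α = 0.05 and power 0.8 the one-sided
solution is 67 matched pairs and the two-sided is 85. The package
defaults to one-sided, which is coherent with a directional linking
hypothesis (only a *positive* correlation of at least 0.3 licenses a
crosswalk) and is the reading that reproduces the conventional 67-pair
requirement; both are available.

## The synthetic cohort

Real matched mHHS/HOOS collections are scarce and not shareable, so the
generator produces cohorts with the statistical structure the analysis
assumes:

- Each patient has a persistent frailty offset (sd 0.06 on the 0–1 latent
  health scale). Each visit's latent trait is
  `trait_mean + shift[t] + patient offset + visit noise`, with pre-op
  mean 0.35 and recovery shifts 0 / 0.20 / 0.33 / 0.40 at pre-op / 3 / 6 /
  12 months.
- Visit-level spread is time-point specific (sd 0.10 / 0.17 / 0.14 /
  0.13): recovery is most heterogeneous at 3 months, when some patients
  have recovered and others have not, so 3-month latent (and score)
  variance exceeds pre-op variance. A per-time-point spread is required
  for this — a pure mean shift cannot change the variance — which is why
  the configuration carries both a shift and an sd per time point.
- Each instrument sees the trait through its own lens: a shared trait
  plus an instrument-specific deviation (`discordance_sd`), reflecting
  the real phenomenon of a patient reporting severe pain on one
  questionnaire and mild pain on the other the same day. Items
  discretise `1 − trait` through equal-width thresholds jittered by
  per-item noise (`item_noise_sd`), the simplest mechanism that yields
  full score-range coverage and the assumed correlation structure.
- Completion is drawn independently per patient-visit (both instruments
  or neither), with default probabilities 35/49, 32/49, 30/49, 24/49 per
  time point; `exact_counts = TRUE` fixes the counts at 35/32/30/24
  (121 matched pairs) for reproducible pipeline runs.

The defaults `discordance_sd = 0.06`, `item_noise_sd = 0.08` were
calibrated once, over a grid of candidate values and ten seeds at 500
visits, so that the Spearman correlation between instrument totals
centres on the configured `target_spearman = 0.9` (seed spread about
±0.02); they were then frozen. `target_spearman` itself is used to
validate configurations — a target of 1 with any positive discordance or
item noise is rejected as impossible.

**What the generator does not emulate:** clinical covariates (age, sex,
diagnosis), informative dropout, item-level missingness patterns,
differential item functioning between instruments, floor/ceiling
clustering beyond what the threshold model produces, and any
centre-specific response style. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline's *mechanics* are correct under
the assumed correlation structure — not that a crosswalk built on any
particular clinical cohort is externally valid.

## Numerical choices and degenerate inputs

- Scores are carried as exact doubles throughout; rounding happens only
  at table export (half away from zero) and presentation.
- EQ requires at least two distinct scores on each side; a constant side
  cannot be rank-inverted and is rejected with an explanation. LR rejects
  zero source variance. The gate requires at least 3 pairs.
- Ties: mid-ranks handle ties on either side symmetrically; identical tie
  structures on both sides make EQ exact at observed scores (asserted in
  the tests).
- The EQ table is passed through a running maximum before range clamping;
  both operations preserve monotonicity, so every exported table is
  non-decreasing and inside the target range by construction.
- Unknown time-point labels, item ids and response codes are rejected by
  name rather than coerced or dropped.

## Problem sizes in the test suite

The suite exercises: oracle equivalence of the EQ implementation against
an independent brute-force rank-matching oracle on samples of up to 30
pairs; monotonicity/range safety over 100 random cohorts; a 121-pair
cohort for the eight-crosswalk pipeline (both methods × both directions ×
HOOS and HOOS-12); 500 visits for the correlation calibration check; and
1200 visits for latent-slope recovery at low noise. These sizes keep each
property statistically meaningful while the whole suite stays fast enough
to run on every change.

## Known limitations

- The HOOS-12 mapping is structural configuration, not a claim about the
  licensed instrument's exact item list; substitute your site's mapping
  before scoring real HOOS-12 data.
- Equated scores carry no confidence intervals; the MAE report is the
  only uncertainty summary.
- No IRT, Tobit/quantile, or Bayesian linking; EQ and LR only.
- Crosswalks are trained on whatever pairs you provide; the package does
  not reweight by time point or case mix.
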