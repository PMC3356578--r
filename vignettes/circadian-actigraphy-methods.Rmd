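---
title: "Methods: circadian actigraphy statistics and the synthetic benchmark"
author: "circact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian actigraphy statistics and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circact)
```

## Scope and design

`circact` implements the analysis battery used to characterize a circadian
behavioural phenotype — the kind of screen that contrasts a mutant mouse
line against wild-type littermates on wheel-running rhythmicity and on the
phase of 24-h biomarker profiles. Animal recordings of that kind are rarely
shareable, so the package is built around a principle: every estimator must
be testable by recovering known parameters from a synthetic generator whose
knobs map one-to-one onto the estimators. The generator is therefore a
first-class, tested module, not a fixture.

## Time conventions

All times are timezone-free elapsed hours from the experiment start; day
*d* spans hours [24·d, 24·(d+1)), with day 0 beginning at the reference
midnight and lights-on defaulting to hour 7 (configurable — acquisition
systems differ and the clock time of lights-on is rarely reported). An
epoch belongs to the lighting state at its start; this is deterministic and
matches the granularity of binned data. Zeitgeber Time is ZT0 at lights-on.
Under DD/LL, ZT is projected from the phase of the last preceding LD
day and flagged as projected in the return value: constant-condition
experiments still label samples with ZT, and a projected axis is the only
coherent way to honour that. A schedule with no LD history has no ZT and
`zt_of()` refuses to invent one.

Sign conventions are package-wide: a phase **advance is positive** (onsets
before lights-off give positive ψ; a schedule advance has positive
`advance_h` and moves lights-off earlier).

## The synthetic generator

`simulate_activity()` is a *descriptive, banded renewal process*, not a
limit-cycle oscillator. A mechanistic oscillator would entangle the
injected parameters (its phase and period would be emergent), whereas the
statistics under test operate on count series and need ground truth that is
exact by construction:

- **Onsets.** Under LD the day-*d* onset sits at lights-off − ψ plus
  N(0, jitter SD); under DD/LL it continues from the previous onset at
  period τ, so the time-of-day drifts by (τ − 24) h/day. After a schedule
  shift of Δ the displacement from the new steady state starts at Δ and is
  multiplied by (1 − r) each day — the simplest monotone (geometric) model
  of gradual re-entrainment, with rate r configurable.
- **Counts.** The nightly band of `active_phase_h` hours is filled by an
  alternating exponential bout/gap renewal process (means `bout_mean_min`,
  `gap_mean_min`); per-epoch intensity is the bout-covered fraction times
  `counts_per_active_epoch`, drawn as Poisson, negative binomial, or
  returned as-is (`"deterministic"`) for exactness tests.
- **Light leak.** A fraction `light_leak_frac` of each day's expected
  counts is relocated uniformly over that day's scheduled-light epochs and
  the band is scaled by the complement, so the expected daily total is
  conserved and the light-phase share of activity equals the leak fraction
  exactly whenever the band lies in darkness. This makes reported
  light-phase percentages (e.g. 19% and 22%) realizable by construction.
- **Masking.** Epochs in unscheduled light (pulses during the dark phase)
  are multiplied by (1 − `masking_coeff`); a coefficient of 1 silences the
  pulse window exactly.

Per-animal seeds in `simulate_cohort()` are derived arithmetically from the
base seed, the group label and the animal index, giving reproducible
cohorts with independent streams.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: ultradian rhythm structure beyond the bout
process, activity-level dependence on running-wheel mechanics or ataxia,
aftereffects of lighting history on τ, transients with overshoot, and any
coupling between fragmentation and phase. Estimator behaviour on real
recordings with such features must be validated separately.

Default study conditions used throughout the tests mirror a typical screen:
10-day LD blocks (periodograms need ≥ 2 full cycles of the longest
candidate period), 10-min epochs, cohorts of 8–12 per genotype, onset
jitter SD 8 min for a well-entrained animal (16 min for the variable
mutant-like preset), a 10-h nightly band, and 6-sample (4-h grid) biomarker
profiles with 4 replicates and noise SD of 0.25 × amplitude. The
`preset_config()` pair ("wildtype_like", "bdr_like") encodes the two
phenotype poles: the mutant-like preset advances ψ by a further ~21.5 min,
doubles onset jitter, shortens bouts (25/25-min bout/gap means versus
150/10) and leaks 19% of activity into the light phase. Published bout
statistics for such mutants are not available in quantitative form, so the
fragmentation defaults are calibrated to reproduce directional contrasts
only, not effect sizes.

## Estimator notes and numerical choices

**IS/IV.** Computed after rebinning to `bins_per_day` (default 24, the
literature's 1-h convention; exposed because source binning conventions
vary). Gap-masked epochs are excluded from means and denominators rather
than zero-filled, which would bias both statistics. Constant series raise a
zero-variance error instead of returning 0/0.

**χ² periodogram.** For candidate period P = K epochs the series is
truncated to the largest whole number m of complete cycles (the standard
Sokolove–Bushell convention; partial cycles bias the column means), and

Q_P = m · N · Σ_h (x̄_h − x̄)² / Σ_i (x_i − x̄)²,  N = m·K,

referred to χ²(K − 1). The m factor matters: without it the statistic's
null expectation is (K − 1)/m and the χ² reference line would be wildly
conservative; with it, simulation confirms a null mean ≈ K − 1 and a
false-positive rate ≈ α (the suite checks 1000 null replicates against a
±2·SE band). The period grid steps by one epoch, so candidate periods are
exact epoch multiples and no interpolation is needed. "Amplitude" is
Q_P minus the α = 0.05 significance line at the peak — the convention of
widely used commercial actigraphy software; it can be negative when no
candidate period reaches significance, which is itself informative.

**Onset detection.** The rule is a template heuristic (published onset
algorithms for this kind of screen are typically unavailable in detail, so
every parameter is surfaced): the onset is the first epoch of the day that
(i) is itself active (≥ the daily mean) at a quiet-to-active transition,
(ii) follows a `quiet_h` = 4-h window with mean below
`frac_threshold` = 0.5 × daily mean and no epoch above daily-mean/0.5, and
(iii) precedes an `active_h` = 1-h window with mean above the daily mean.
The burst guard (ii) prevents mid-band lulls of fragmented nights from
being read as onsets; the asymmetry between (ii) and (iii) keeps the rule
stable on transition days carrying two activity bands (e.g. the day of a
schedule advance). Days with no qualifying epoch are flagged, never
imputed.

**τ regression.** Onset times are regressed on a circadian *cycle index*
rather than the calendar day: the integer number of cycles between
successive onsets is assigned by rounding the inter-onset interval by the
running τ estimate (three fixed-point iterations from 24 h). Day-indexed
unwrapping aliases whenever an onset drifts across midnight and a calendar
day is skipped; cycle indexing recovers τ exactly on noiseless drift for
any τ in the supported 20–28 h range. The CI is the OLS slope CI — adequate
for Gaussian onset jitter, slightly anticonservative when detection error
is epoch-quantized (coverage in the test conditions is ≈ 90–95%).

**Phase shifts and re-entrainment.** Shifts are quantified as the
difference of pre- and post-event onset regression lines evaluated at the
event day (post window after discarding a transient), wrapped to ±12 h —
an onset-translation quantification rather than a full Aschoff Type I
protocol. Re-entrainment time is the first post-shift day from which ψ
stays within `criterion_min` of its pre-shift steady state for
`consecutive_days` running; a record that never satisfies the criterion
returns NA with a warning rather than a fabricated day.

**Bouts.** Threshold/merge/minimum rules with defaults (1 count per 10-min
epoch, 30-min merge gap, 10-min minimum) stated in configuration, not
hard-coded, because published bout definitions vary; the fragmentation
contrast between presets is sharper with a merge gap below the mutant-like
gap mean (the tests use 20 min) — with a 30-min gap the mutant's 25-min
gaps are largely absorbed.

**Cosinor.** The fit is exact linear least squares on the cos/sin basis;
amplitude and acrophase follow from the rectangular coefficients, and
rhythm detection is the 2-df F test against the intercept-only model. A
constant profile returns amplitude 0 with an undefined-flagged acrophase
instead of erroring, so screens over many profiles degrade gracefully.
Replicates are treated as independent cross-sectional observations at
their ZT, matching the n-per-timepoint design of SCN immunohistochemistry
and hormone time courses; a random-effects population cosinor is out of
scope. For coarse 4-h grids the model-free `peak_bin()` (argmax of bin
means, ties to the earliest ZT, flagged) matches how such profiles are
usually reported, while the cosinor supports recovery and inference; the
two are complementary and both are exposed.

**Group comparison.** `compare_groups()` wraps the pooled-variance t test
and the one-way-ANOVA planned comparison (identical for two groups), and
the pipeline reports raw per-metric p values by default — matching common
practice in phenotype screens — with Holm adjustment available by a flag.

## Pipeline reproducibility

`run_pipeline()` stamps every CSV with the seed and an MD5 hash of the full
effective configuration (excluding the output directory), and rerunning
with the same configuration reproduces outputs byte for byte. The bundled
demonstration contrasts the two presets across every battery metric and on
ZT6- versus ZT10-peaking profiles.

## Known limitations

- The onset detector is a heuristic; pathological records (arrhythmia,
  near-12-h components, extreme leak) can defeat it, and flagged-day rates
  should be inspected.
- τ estimation assumes a single stable period; split rhythms and
  relative coordination are not modelled.
- The light-leak construction fixes the *expected* light-phase share;
  stochastic count models realize it only in expectation.
- AWD support covers the common epoch codes (15 s–5 min); 10-min data
  round-trip through the long CSV dialect instead.
- Actograms are presentational; no statistics are computed from the
  rendering path.
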