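# circact

Circadian actigraphy analysis and simulation for the kind of study that
characterizes a mouse mutant's rest-activity phenotype: wheel-running
recordings under light/dark (LD), dim-LD, constant-dark (DD) and
constant-light (LL) protocols, plus sparsely sampled 24-h biomarker
profiles (SCN neuropeptides, serum hormones). It is aimed at chronobiology
labs and at methodologists who need every estimator in the battery to be
verifiable by parameter recovery on synthetic data.

## What it computes

For an activity-count series *x₁…x_N* binned at a fixed epoch and a lighting
schedule defining Zeitgeber Time (ZT0 = lights-on):

- **Light-phase activity share** — 100·(counts in scheduled light)/(total),
  over complete LD days.
- **Interdaily stability (IS)** — with *p* bins/day and across-day bin means
  x̄_h: `IS = N Σ_h (x̄_h − x̄)² / (p Σ_i (x_i − x̄)²)`; 1 for a perfectly
  repeated daily profile, ≈ p/N for noise.
- **Intradaily variability (IV)** —
  `IV = N Σ (x_i − x_{i−1})² / ((N−1) Σ (x_i − x̄)²)`; ≈ 0 smooth, ≈ 2 white
  noise, 4 strict alternation.
- **Activity bouts** — threshold/merge/minimum-duration runs, and bouts/day.
- **χ² periodogram (Sokolove–Bushell)** — for period *P* = *K* epochs folded
  over *m* complete cycles, `Q_P = m·N·Σ_h (x̄_h − x̄)² / Σ_i (x_i − x̄)²`,
  referred to χ²(K−1); *amplitude* = Q_P minus the α = 0.05 significance
  line at the peak period.
- **Phase angle of entrainment (ψ)** — daily activity onset (template
  detector) relative to lights-off, in minutes; positive = advanced.
- **Free-running period (τ)** — regression of onset times on circadian
  cycle index under DD/LL, or the periodogram peak.
- **Phase-shift magnitude, re-entrainment time, negative-masking index** —
  jet-lag and light-pulse paradigms quantified on the onset series.
- **Cosinor rhythmometry** — least-squares fit of
  `y = M + A·cos(2π(t − φ)/24)` for mesor *M*, amplitude *A*, acrophase φ,
  with a zero-amplitude F test; plus a model-free `peak_bin()` and circular
  group phase differences.

A seeded generator (`sim_config()`, `simulate_activity()`,
`simulate_cohort()`, `simulate_profile()`) produces activity series and
biomarker profiles with all of these quantities injected as ground truth —
entrained or free-running onsets, bout/gap fragmentation, light-phase
activity leak, negative masking, geometric re-entrainment after a schedule
advance, and sinusoidal profiles with chosen acrophase.

## Worked example

Simulate a fragmented, phase-advanced animal and run the battery:

```r
library(circact)
sched <- ld_schedule()                         # 12:12 LD, lights on 07:00
a <- simulate_activity(preset_config("bdr_like", seed = 7), sched, 10,
                       subject_id = "demo", group = "bdr_like")

light_phase_activity_pct(a, sched)   # 23.8  (% of counts in the light phase)
interdaily_stability(a)              # 0.575 (1 = perfectly repeated days)
intradaily_variability(a)            # 0.889 (2 would be white noise)
chi_square_periodogram(a)
#> peak 24 h: Qp = 500.9, significance line 171.9, amplitude 329.0
phase_angle_entrainment(detect_onsets(a), sched)
#> psi = +40.00 +/- 7.07 min over 9 day(s) (positive = advanced)
```

The injected preset leaks 19% of daily counts into the light phase and
advances the onset by ~30 min; the measured 23.8% and +40 min include the
sampling noise of a single 10-day animal (cohort means recover the injected
values much more tightly — see the tests). A biomarker profile with a ZT6
peak is recovered by both peak calls:

```r
p <- simulate_profile(acrophase_h = 6, mesor = 2, amplitude = 1,
                      sample_zts = seq(2, 22, 4), n_reps = 4,
                      noise_sd = 0.25, seed = 101)
peak_bin(p)                          # 6
cosinor_fit(p)
#> mesor 1.967, amplitude 1.137, acrophase ZT 6.08 h  (F = 199, p = 2.2e-14)
```

`run_pipeline()` chains all of this for a labelled two-group cohort and
writes per-subject metrics, periodograms, phase estimates, cosinor fits and
actograms as stamped CSVs that reproduce byte-for-byte from (config, seed).

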