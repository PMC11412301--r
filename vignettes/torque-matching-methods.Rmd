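---
title: "Torque-matching psychophysics and muscle synergies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torque-matching psychophysics and muscle synergies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

When a person generates an isometric elbow flexion torque while
simultaneously abducting the shoulder, both the *generation* of that torque
(its steadiness, the antagonist coactivation about the elbow, the time taken
to stabilize it) and the *perception* of it (how accurately and consistently
it can be reproduced from memory) may depend on the shoulder load. The
experimental paradigm this package analyzes is a two-phase torque-matching
trial: in the **reference phase** the participant abducts the shoulder to a
prescribed fraction of their maximum voluntary shoulder abduction torque
(MVT~SABD~), then flexes the elbow to 25% of their maximum voluntary elbow
flexion torque (MVT~EF~) under visual feedback and memorizes it; in the
**match phase**, after a 6 s gap, they reproduce the elbow torque without
feedback and without abducting the shoulder (trials in which match-phase
shoulder torque reaches 10% MVT~SABD~ are restarted). Multichannel surface
EMG (8 muscles spanning elbow flexion/extension and shoulder abduction) and
both joint torques are recorded at 1 kHz.

`torquematch` implements every analysis stage for this paradigm, plus a
synthetic cohort generator so that the full pipeline is testable end to end
with no external recordings.

## Pipeline overview

1. **Simulation** (`generate_cohort`): cohorts of trials with known injected
   structure (perceptual bias per load, motor noise, ground-truth synergies).
2. **EMG envelopes** (`process_channel`): zero-phase 250 Hz low-pass,
   zero-phase 60 Hz notch, full-wave rectification, 250 ms sliding RMS,
   normalization to the MVC peak (percent MVC).
3. **Torque features** (`trial_features`): reference/match torques from
   fixed 0.5 s segments, force-steadiness CV, flexor–extensor coactivation,
   stabilization time T~ref~, validity flags.
4. **Perception** (`perception_outcomes`): constant error
   CE = mean(τ~match~ − τ~reference~) and variable error VE = SD of the same,
   per participant × load, over valid trials.
5. **Synergies** (`assemble_matrix`, `normalize_matrix`,
   `select_synergy_count`, `random_synergy_threshold`, `match_synergies`):
   NMF of the 8 × 48 activity matrix, minimal synergy count reaching 95%
   VAF, chance-similarity threshold from 10^6^ random-synergy scalar
   products, cross-participant matching.
6. **Associations** (`correlate_features`): Spearman rank correlations of
   CV, coactivation and T~ref~ against the per-trial matching error, with
   exact permutation p-values at these sample sizes.

## Segment and estimator conventions

Several conventions are not forced by the paradigm itself; they are fixed
here so that results are exactly reproducible:

- **Windows are half-open** `[start, end)`, mapped to sample indices by
  flooring `start × fs`. The reference segment is the 0.5 s after the
  reference-phase "hold" cue; the match segment runs from 0.25 s before to
  0.25 s after the match-phase "hold" cue.
- **Sample SD** (n − 1 denominator) is used everywhere: the CV, VE, and the
  unit-variance normalization stage.
- **T~ref~** is the "in"→"hold" cue interval of the reference phase. (An
  alternative reading, "in"→"relax", differs by the fixed 1 s hold and is
  not used.)
- `compute_cv` is undefined (NA) for non-positive segment means;
  `compute_coactivation` for zero summed activity. Downstream stages treat
  NA features by dropping the affected cell, never by imputation.

## EMG preprocessing choices

The filter family and order are a design choice: a 4th-order Butterworth
low-pass applied forward–backward (zero phase, effective 8th order), and a
2nd-order IIR notch biquad at 60 Hz with Q = 30, also applied
forward–backward. Both are standard choices for surface EMG; correctness is
asserted against frequency-response oracles (unit DC gain, ≤10% leakage at
400 Hz, ≤5% 60 Hz residual, ≤2% passband droop at 10 Hz) rather than
coefficient equality, so any filter meeting the response contract would
pass. Forward–backward application needs edge handling: signals are padded
by odd reflection long enough for the filter's settling time (the Q = 30
notch rings for roughly `2Q/ω0` ≈ 0.16 s), so edge transients decay inside
the padding. The RMS window is centered and truncated at the edges, which
preserves length and avoids group delay. Envelopes are reported in percent
MVC.

## The activity matrix and NMF

Per participant, the mean percent-MVC envelope of each muscle in each
analyzed segment forms an 8 × 48 matrix (2 phases × 8 testing trials × 3
loads), columns ordered load-ascending, trial-ascending,
reference-before-match. Rows are normalized in two stages — divide by the
row maximum (range 0–1), then by the row sample SD (unit variance) — with
the combined factors recorded for inversion.

NMF minimizes the squared Frobenius reconstruction error with the classical
multiplicative updates; the algorithm itself fixes no hyperparameters, so
these are declared: 20 random restarts, tolerance 10^−6^ on the relative
objective decrease, at most 2000 iterations, best restart kept, synergy
vectors unit-normalized with the scale absorbed into H. VAF is **uncentered**
(1 − SSE/‖A‖²~F~), the dominant convention in the synergy literature; a
grand-mean-centered variant is available behind `centered = TRUE` for
sensitivity analysis. The synergy count is the smallest n (1…8) whose VAF
reaches 95%.

The chance-similarity threshold draws 1000 random synergies with
coordinates Uniform(0, 1) scaled to unit norm — nonnegative and unbiased
within the positive orthant — and takes the 95th percentile of all 1000²
ordered pairwise scalar products. Self-pairs are included so the
distribution size is exactly 10^6^ (0.1% of the mass, shifting the 95th
percentile negligibly); `include_self = FALSE` provides the sensitivity
variant. Cross-participant matching is greedy best-first on the scalar
product against one reference participant's synergies, each reference
synergy used at most once per participant; an exhaustive optimal assignment
is available (`method = "optimal"`) and agrees with the greedy rule on
clean cohorts. Tie behavior under greedy matching is first-encountered
maximum, which is deterministic given the fixed column order.

## Spearman correlations

rho is the Pearson correlation of mid-ranks (average ranks under ties). For
n ≤ 8 the two-sided p-value is exact: the fraction of all n! permutations
whose |rho| reaches the observed |rho|. Above that, the usual
t-approximation is used. The exact path matches independent brute-force
enumeration and `stats::cor.test`'s exact distribution in the test suite.
With 8 testing trials per cell the smallest attainable two-sided p is
2/8! ≈ 5 × 10^−5^; reported p-values are interpretable without
multiple-comparison correction, which is deliberately not applied here.

## What the generator emulates — and what it does not

Defaults are the emulated study's conditions: 19 participants; MVT~EF~
48.7 ± 18.3 Nm and MVT~SABD~ 54.5 ± 24.0 Nm (truncated normal, floored at
10 Nm to exclude nonphysical strengths); loads 10/30/50% MVT~SABD~; elbow
target 25% MVT~EF~ with a ±5% acceptance band; 10 trials per block with the
first two practice (practice trials get doubled motor noise and are
excluded); injected constant error 0.34/1.85/3.77 Nm per load; match noise
SD 2 Nm; torque-hold CV 1.5%; T~ref~ 6.44 ± 2.22, 3.86 ± 1.24 and
3.65 ± 1.69 s per load, truncated at 0.5 s.

Values the emulated protocol does not state are declared once: the "up" cue
at 0.5 s, a 2 s shoulder ramp, the "in" cue 2.5 s after "up", a match-phase
stabilization time ~ N(3, 1) s truncated at 1 s, and trial end 0.5 s after
the final cue. The match-phase shoulder residual is drawn at 1–6% MVT~SABD~
and clipped strictly below the 10% restart bound, so generated cohorts
contain no restarted trials.

Raw EMG is synthesized as band-limited (20–450 Hz) Gaussian noise,
amplitude-modulated by the programmed envelope `W·h(t)` — `W` the
ground-truth synergy matrix (default: an elbow synergy loading
biceps/triceps and a shoulder synergy loading the deltoids, pectoralis
major and trapezii), `h(t)` the normalized torque drives — plus a 60 Hz
line component (5% relative amplitude) and a 1% broadband noise floor.
Each synergy's drive also carries per-phase multiplicative lognormal gain
variability (CV 15%), emulating the well-documented trial-to-trial
fluctuation of EMG amplitude at constant force. This term matters: without
it, elbow-muscle activity is nearly identical across all 48 matrix columns,
and after unit-variance row normalization a *single* synergy already
reconstructs the matrix beyond 95% uncentered VAF, so no two-synergy regime
exists to recover.

The generator does **not** model limb biomechanics, motor-unit physiology,
fatigue, electrode artifacts beyond mains interference, or any coupling
between the torque-generation features and the matching error — CV,
coactivation and T~ref~ are independent of τ~err~ by construction, so the
correlation stage should (and does) find significant cells at roughly the
nominal 5% rate. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline recovers known injected structure, not that real data
would show any particular effect.

One identifiability property of the paradigm is worth knowing when
interpreting synergy output: in the two analyzed segments the shoulder
synergy is never active without concurrent elbow activity, so its extracted
vector necessarily carries a small elbow-muscle component (cosine ≈ 0.9
against the programmed vector), whereas the elbow synergy — appearing
nearly alone in match-phase columns — is recovered beyond the chance
threshold (≈ 0.92). Factor recovery at the matrix level (activity built
directly as W·H plus ≤5% rectified noise) exceeds 0.9 cosine for both
synergies, confirming the limitation comes from the protocol's activation
structure, not the factorization.

## Problem sizes and determinism

Everything is deterministic given the seeds: cohort generation pre-draws
per-trial seeds under the master seed; NMF restarts and the similarity null
are seeded. The analysis drivers under `analysis/` use a 19-participant
cohort; the test suite exercises the same code paths on 1–2-participant
cohorts with EMG, a 50-participant torque-only cohort for perceptual
recovery, and 200-trial-per-load torque-only runs for bias recovery —
sizes chosen so each suite file completes in seconds while leaving Monte
Carlo tolerances (3 SE, binomial 99% bands) meaningful.

## Known limitations

- Cue events are metadata, never detected from signals; recordings lacking
  an event are flagged invalid rather than repaired.
- The EMG model is an amplitude-modulated carrier: it exercises every
  preprocessing stage but has no motor-unit structure, so it cannot
  validate decomposition methods finer than envelope analysis.
- The mixed-effects inference across loads is intentionally out of scope;
  the per-trial and per-cell TSV exports are designed to be consumed by any
  external stats environment.
- The uncentered-VAF criterion, like all fixed-threshold model selection,
  is sensitive to the normalization convention; both stages of the row
  normalization are therefore part of the contract, and `normalize_matrix`
  records its scales so results can be mapped back to percent MVC.
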