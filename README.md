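# torquematch

Analysis pipeline for two-phase isometric **elbow torque-matching**
experiments under concurrent shoulder abduction loads, with multichannel
surface EMG — and a synthetic cohort generator that makes every stage
testable without any recordings.

## The scientific problem

In the paradigm this package analyzes, a participant abducts the shoulder
to a prescribed load (10/30/50% of maximum voluntary shoulder abduction
torque, MVT<sub>SABD</sub>), generates and memorizes an elbow flexion
torque at 25% of maximum voluntary elbow flexion torque (MVT<sub>EF</sub>)
under visual feedback (*reference phase*), then reproduces it from memory
without feedback and without abducting (*match phase*). The analysis asks
two questions:

1. **How is the torque generated?** Force steadiness as the coefficient of
   variation CV = SD/mean of the held torque; flexor–extensor coactivation
   as EMG<sub>tri</sub>/(EMG<sub>bic</sub> + EMG<sub>tri</sub>) × 100% of
   normalized activity; stabilization time T<sub>ref</sub>; and the muscle
   coordination as **muscle synergies**: nonnegative matrix factorization
   A ≈ W₁H₁ + … + WₙHₙ of the 8 × 48 activity matrix (8 muscles; 2 phases ×
   8 trials × 3 loads), selecting the minimal n whose variance accounted
   for, VAF = 1 − ‖A − WH‖²<sub>F</sub>/‖A‖²<sub>F</sub>, reaches 95%.
   Synergies are compared across participants against a chance-similarity
   threshold: the 95th percentile of the 10⁶ pairwise scalar products of
   1000 random unit-norm synergies.
2. **How is the torque perceived?** Constant error
   CE = mean(τ<sub>match</sub> − τ<sub>reference</sub>) and variable error
   VE = SD(τ<sub>err</sub>) per participant × load, and Spearman rank
   correlations (exact permutation p-values at n ≤ 8) between each
   generation feature and the per-trial matching error.

The EMG chain is the standard envelope pipeline: zero-phase 250 Hz
low-pass, zero-phase 60 Hz notch, full-wave rectification, 250 ms sliding
RMS, normalization to the MVC peak.

## Worked example

```r
library(torquematch)

cfg <- generator_config(n_participants = 1, seed = 11)
cohort <- generate_cohort(cfg)            # torques + 8-channel EMG at 1 kHz
f <- features_table(cohort)               # per-trial features
am <- normalize_matrix(assemble_matrix(f))
m <- select_synergy_count(am, seed = 5)
print(m)
#> <synergy_model> P01: n = 2, VAF = 99.9%
#>   VAF curve: 0.859 0.999 1.000 1.000 1.000 1.000 1.000 1.000
perception_outcomes(f)
#>   participant load     ce_nm    ve_nm n_trials
#> 1         P01  0.1 -1.036832 2.124274        8
#> 2         P01  0.3  2.242743 1.656670        8
#> 3         P01  0.5  2.426471 1.503150        8
```

One synergy reconstructs only 85.9% of the activity matrix; two reach
99.9%, so the minimal-count rule at the 95% VAF criterion selects **n = 2**
— the generator's ground truth (an elbow flexion/extension synergy and a
shoulder abduction synergy). The perceptual table shows the constant error
per load (Nm, positive = overshoot when matching from memory) and its
trial-to-trial SD, each over the 8 valid testing trials.

The full cohort analysis is organized as numbered drivers:

```sh
Rscript analysis/01_simulate.R          # 19 participants, writes results/features.tsv
Rscript analysis/02_torque_features.R   # CV / coactivation / T_ref per load
Rscript analysis/03_perception.R        # CE / VE per load
Rscript analysis/04_synergies.R         # NMF, VAF selection, group matching
Rscript analysis/05_correlations.R      # Spearman grid vs matching error
```

On the default cohort these report, e.g., CE rising with load
(+0.31 / +2.15 / +4.14 Nm), T<sub>ref</sub> longest at the lightest load
(6.26 / 3.58 / 3.54 s), two synergies for all 19 participants
(VAF 99.9 ± 0.0%) that all cross-match above the 0.919 chance threshold,
and feature–error correlations significant at roughly the nominal 5% rate
(the generator injects no such coupling).

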