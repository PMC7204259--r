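# synergydecode

Continuous estimation of two-dimensional wrist angle and grip force from
multichannel surface-EMG envelopes via **muscle synergies** — fixed
nonnegative weighting patterns across muscles that the nervous system
recruits as units. The pipeline:

1. **Preprocess** raw EMG into *quasi-tension* envelopes: rectify, low-pass
   with a 2nd-order 5 Hz Butterworth filter, clip to nonnegative, normalize
   each channel by its peak over the whole session, and resample to a common
   74 Hz grid.
2. **Extract synergies** by nonnegative matrix factorization using
   hierarchical alternating least squares (HALS): `E ≈ M Sᵀ` with `E` the
   time × channel envelope matrix, `S` the channel × j synergy loadings
   (unit-norm columns) and `M` the time × j activations. Two strategies are
   supported: `"joint"` (one factorization of the pooled wrist-movement and
   grip trials, the grip synergy labeled afterwards by its finger-flexor
   loading) and `"separate"` (independent factorizations per trial type).
3. **Select the synergy count** as the smallest j whose minimum
   variance-accounted-for (VAF) over all training datasets reaches 0.9.
4. **Decode**: project new envelopes onto the frozen synergy basis by
   nonnegative least squares, map activations to normalized sum/difference
   wrist coordinates (`u = x/max_x + y/max_y`, `v = x/max_x − y/max_y`) with
   one ordinary-least-squares regression fitted on a wrist training trial
   plus a grip training trial (zero-angle reference), and read grip force
   directly off the calibrated grip-synergy activation.
5. **Evaluate** by exhaustive cross-validation over every
   (wrist training trial × grip training trial) pair, reporting Pearson r
   and RMSE normalized by the 90° wrist range (nRMSE).

A synthetic-session generator with known ground-truth synergies emulates a
seven-muscle forearm protocol (ECR, ECU, FCU, FCR, APL, FDS, FDP) across
eight task conditions, so the full pipeline can be exercised and validated
without laboratory recordings. See the methods vignette
(`vignettes/synergy-decoding.Rmd`) for the model, assumptions and design
rationale.

## Worked example

```r
library(synergydecode)

gt       <- make_ground_truth(seed = 1, snr_db = 20)   # 4 wrist + 1 grip synergy
session  <- generate_session(gt, default_protocol(n_trials = 3, n_reps = 3),
                             seed = 2)                 # 24 trials, 8 conditions
prep     <- preprocess_session(session, zero_phase = TRUE)

# synergy count from the VAF >= 0.9 rule on the wrist training trials
conds <- vapply(prep$trials, `[[`, "", "condition")
sel <- select_synergy_count(lapply(prep$trials[conds == "comfortable_max"],
                                   `[[`, "E"))

report <- exhaustive_cv(prep, strategy = "separate", j_wrist = 4)
print(report)
```

On this session (seed 1 ground truth, 20 dB SNR) the report is:

```
decoder performance (separate extraction, 4 wrist + 1 grip synergies, 9 folds)
  wrist_r            0.9967 +/- 0.0001
  wrist_nrmse        0.0138 +/- 0.0002
  grip_angle_nrmse   0.0049 +/- 0.0001
  grip_force_r       0.9802 +/- 0.0001
```

Sweeping the synergy count shows the expected rise to the generator's four
wrist synergies and a mild degradation beyond it
(`synergy_number_sweep(prep, 1:6)`):

```
 j   wrist_r  wrist_nrmse  grip_angle_nrmse
 1  0.190       0.166          0.0215
 2  0.711       0.119          0.0147
 3  0.968       0.043          0.0051
 4  0.9967      0.0138         0.0049
 5  0.9967      0.0138         0.0055
 6  0.9967      0.0138         0.0055
```

(On this noisy session the VAF ≥ 0.9 rule selects `sel$j = 3` — the VAF
criterion is deliberately conservative and can sit one below the count at
which decoding performance saturates; the sweep above is the complementary
diagnostic.)

Separate extraction is more robust than joint extraction on grip trials
(grip-trial angle nRMSE 0.0049 vs 0.0063, paired t-test p ≈ 8e-12 across the
nine folds), and maximum-force grips perturb the decoded wrist angle more
than quarter-force grips (nRMSE 0.0078 vs 0.0021) — both produced by
`analysis/04_decoding_performance.R` and `analysis/05_grip_force.R`.

## Repository layout

- `R/` — the package: generator, preprocessing, angle transform, HALS NMF,
  decoder, evaluation, text-stream I/O, and a config-driven `run_all()`.
- `analysis/01…05_*.R` — numbered `Rscript` drivers reproducing the study
  workflow end to end; each writes plain TSV tables under `results/`.
- `tests/testthat/` — unit and end-to-end property tests, including
  independent oracle checks of the NMF objective and the metrics.
- `scripts/acceptance.R` — one-shot pipeline run that writes the headline
  quantities as JSON.

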