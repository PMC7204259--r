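---
title: "Synergy-based decoding of wrist angle and grip force: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synergy-based decoding of wrist angle and grip force: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `synergydecode`, the
assumptions behind it, the numerical choices, and the rationale for the
places where a design decision had to be made. Code chunks are illustrative
and not evaluated when the package is built.

## 1. The decoding model

Surface EMG from `n = 7` forearm muscles (ECR, ECU, FCU, FCR, APL, FDS,
FDP) is reduced to *quasi-tension* envelopes and modeled as a nonnegative
mixture of a small number of **muscle synergies**:

$$E \approx M S^\top, \qquad E \in \mathbb{R}_{\ge 0}^{T \times n},\;
M \in \mathbb{R}_{\ge 0}^{T \times j},\; S \in \mathbb{R}_{\ge 0}^{n \times j}.$$

`S` holds fixed per-muscle loadings (unit-norm columns; the scale lives in
`M`), `M` the time-varying neural drive to each synergy. Wrist angle is
decoded as an affine function of the activations, grip force as a scaled
single activation:

- Angles are first mapped to normalized **sum/difference coordinates**
  `u = x/max_x + y/max_y`, `v = x/max_x − y/max_y`, where `x` is
  flexion/extension and `y` radial/ulnar deviation and the maxima are the
  per-axis absolute maxima of the *wrist training trial only* (frozen at fit
  time, like any other decoder parameter; `fit_normalization()`).
  The transform is linear and exactly invertible (`to_sum_diff()`,
  `from_sum_diff()`), and in these coordinates antagonistic synergy pairs
  contribute with opposite signs, which is what makes a *linear* map from
  nonnegative activations to signed angles plausible.
- `fit_decoder()` fits one ordinary-least-squares regression
  `(u, v) ~ 1 + M` and calibrates the grip gain so that the grip synergy's
  peak activation on the grip training trial corresponds to normalized
  maximum force 1. `estimate_grip_force()` is that scaled activation — no
  second regression.

### Why the regression sees both training trials

The decoder is calibrated from **two** trials: a wrist-movement trial (with
its measured angles) and a grip trial, which enters the regression with a
zero-angle reference because the hand is stationary while gripping. On a
wrist-only trial the grip synergy's activation is essentially zero, so its
angle coefficient would be unconstrained by the data; in early testing the
unidentified coefficient extrapolated catastrophically on held-out grip
trials (angle nRMSE orders of magnitude above 1). Pooling the grip trial
pins that coefficient near zero and is the only configuration in which the
model is identified. `include_grip_regressor = FALSE` removes the grip
activation from the angle regression entirely, which is the other defensible
choice; the default keeps it so that systematic grip-related leakage into
wrist channels can be linearly compensated.

## 2. Preprocessing

`preprocess_session()` performs, per channel:

1. rectification (`abs`),
2. 2nd-order Butterworth low-pass at 5 Hz (`signal::butter`), causal
   (`signal::filter`) or zero-phase (`signal::filtfilt`, default in the
   analysis scripts),
3. clipping of filter undershoot to 0,
4. normalization by the channel's peak over the *whole session* ("task
   peak"), so every envelope is in [0, 1] with a physiologically comparable
   scale across muscles,
5. linear resampling (`stats::approx`) of envelopes, angles and force to a
   common 74 Hz grid.

Choices worth noting:

- **Causal vs zero-phase.** A real-time decoder must be causal; offline
  analysis prefers zero-phase filtering (no group delay, so envelopes and
  kinematics stay aligned). Both are exposed via `zero_phase`; the
  filter magnitude response is identical (squared for zero-phase), and
  `envelope_filter_response()` returns the analytic response used in the
  tests: unity DC gain, −3.01 dB at 5 Hz, > 50 dB attenuation at 100 Hz for
  2000 Hz sampling.
- **Normalization scope.** Peaks are computed over all trials of the
  session, not per trial: per-trial normalization would rescale identical
  muscle activity differently across conditions and destroy the fixed-`S`
  assumption. A channel with zero session peak is an electrode failure and
  raises an error naming the channel.

## 3. Synergy extraction: HALS NMF

`hals_nmf()` minimizes the Frobenius reconstruction error by
**hierarchical alternating least squares**: each column of `S` (then of `M`)
is updated in turn by a projected one-dimensional least-squares step,

$$s_k \leftarrow \Big[ s_k + \frac{(E^\top M - S M^\top M)_{\cdot k}}{(M^\top M)_{kk}} \Big]_+,$$

with the Gram matrices computed once per half-sweep. Columns whose Gram
diagonal collapses below `eps` are zeroed (dead-column guard). The solver
runs `n_restarts` times (default 10) from seeded uniform initializations
scaled by `sqrt(mean(E)/j)` — this scaling makes the whole trajectory
exactly scale-equivariant, so scaling `E` by `c` scales `M` by `c` and
leaves the unit-norm `S` unchanged — and keeps the best objective.
Convergence is declared when the relative objective decrease falls below
`tol` (default 1e-8). HALS converges markedly faster than
multiplicative-update NMF on these small dense problems; the test suite
nevertheless checks the converged objective against an independently
implemented multiplicative-update oracle, which exists only inside the
tests.

Two extraction strategies mirror the two calibration designs studied:

- `extract_synergies_separate()` — wrist synergies from the wrist training
  trial, the grip synergy from the grip trial, each with its own
  factorization. The grip synergy cannot absorb wrist variance and vice
  versa.
- `extract_synergies_joint()` — one factorization of the pooled trials at
  `j_wrist + j_grip`; the grip column is identified *post hoc* as the one
  with the largest relative FDS+FDP (finger flexor) loading.

`project_activations()` computes activations for new data with `S` frozen:
a `MASS::ginv` warm start followed by HALS sweeps on `M` only — a
deterministic nonnegative least-squares solve, the same operation a
real-time decoder would run per sample window.

**Synergy count.** `select_synergy_count()` factorizes each training
dataset over `j = 1…6` and `select_from_vaf_table()` picks the smallest `j`
whose *minimum* VAF across datasets reaches 0.9, where VAF is the
uncentered variance accounted for,
`1 − ‖E − M Sᵀ‖²_F / ‖E‖²_F`. Uncentered VAF is the standard criterion for
nonnegative envelope data (the mean level is signal, not offset). Matching
estimated to ground-truth synergies in the tests uses exhaustive
permutation search over cosine similarity — exact and trivially affordable
at `j ≤ 8`, avoiding a Hungarian-algorithm dependency.

## 4. Evaluation

`exhaustive_cv()` enumerates every (wrist training trial × grip training
trial) pair as a fold, refits extraction and decoder per fold, and
evaluates all remaining trials. Wrist-movement trials report per-axis
Pearson r and pooled nRMSE against the measured angles; grip-only and
force-tracking trials report nRMSE of the decoded angle against the
**zero-angle reference** — any decoded excursion during a stationary grip is
a perturbation — plus the correlation between estimated and true grip
force. nRMSE divides the pooled RMSE by `a = 90°`, the wrist range.
`compare_models()` wraps Student's t-test for fold-level comparisons (no
multiple-testing adjustment; the analysis scripts run single planned
comparisons).

## 5. The synthetic generator

`make_ground_truth()` + `generate_session()` emulate a seven-muscle,
eight-condition recording protocol with known mixing:

- **Synergies.** Four direction-tuned wrist synergies — extension
  (ECR/ECU/APL), flexion (FCU/FCR), radial (ECR/FCR/APL), ulnar (ECU/FCU) —
  plus one grip synergy on FDS/FDP with bounded spillover onto wrist
  channels (`grip_spillover`). Loadings get per-seed log-normal jitter and
  unit-norm columns.
- **Activations.** Each wrist synergy is a rectified cosine of movement
  direction in normalized angle space,
  `m_k = [cos φ_k · x̂ + sin φ_k · ŷ]_+` (+ small tonic drive), with
  `φ ∈ {0°, 180°, 90°, 270°}`. This keeps `u` and `v` *exactly affine* in
  the activations (`u = m_ext − m_flex + m_rad − m_uln` up to the tonic
  bias), so a linear decoder is correct by construction, while giving each
  synergy solo-activation epochs that make the factorization identifiable.
  A literal sum/difference drive (two signed coordinates split into four
  rectified channels) was rejected: it produces rank-3 envelope data for
  axis-aligned movements and no solo activations, so no factorization
  method could recover four distinct wrist synergies from it.
- **Kinematics.** Raised-cosine out-and-back movements along the axis and
  diagonal directions (±`diagonal_bias` jitter), 45° amplitude at the
  comfortable maximum, 0.5 s lead/rests, all segment lengths multiples of
  0.5 s so sample counts are integral at 2000/100/74 Hz. Grip force is a
  trapezoidal pulse profile; grip-only trials hold the wrist at zero.
- **Noise.** Envelope noise is *band-limited*: white Gaussian noise shaped
  by the same zero-phase 5 Hz Butterworth, rescaled to the target `snr_db`,
  added, and clipped at 0. White noise added at the EMG rate would be
  almost entirely removed by the 5 Hz preprocessing filter (an effective
  +20 dB), making nominal SNR meaningless and hiding the
  overfitting penalty of extracting too many synergies; envelope-level
  disturbances (baseline wander, motion artifact residue, crosstalk) are
  low-frequency by nature.
- **Nonlinear contamination.** `grip_crosstalk` adds a *quadratic*
  grip-driven term to the wrist channels. Because it is nonlinear in the
  grip activation, a linear decoder cannot fully compensate it — this is
  what produces the realistic trends that strong grips perturb the decoded
  wrist angle more than weak grips, and that separate extraction is more
  robust than joint extraction on grip trials.

### Realism and limits

The generator matches the *structure* of forearm recordings (muscle set,
task protocol, rates, synergy organization, SNR regime), not their
statistics: real EMG envelopes have signal-dependent noise, slow
electrode drift, fatigue-related nonstationarity, and subject-specific
synergy counts. Quantities computed on synthetic sessions therefore
validate the pipeline's correctness and reproduce qualitative trends; they
are not predictions of human-subject performance (held-out wrist r on
clean synthetic data is ≈ 0.997, far above what real recordings yield).

## 6. Numerical choices

- Problem sizes used throughout (50–600 samples × 7 channels, `j ≤ 6`) make
  dense `qr`/`crossprod` linear algebra the right tool; no sparse or
  iterative solvers are needed.
- OLS uses `qr()`; rank-deficient designs warn and fall back to the
  `MASS::ginv` minimum-norm solution rather than silently dropping columns.
- Determinism: every stochastic step (ground truth, trial schedules, noise,
  HALS restarts) is driven by explicit seeds; regenerating a session or
  refitting with the same configuration is bit-identical, and `run_all()`
  stamps every output table with the MD5 hash of the producing
  configuration.
- All artifacts are plain text (TSV with `#` headers, YAML manifests) so
  sessions and results are diffable and inspectable.

## 7. Reproducing the study workflow

```{r, eval = FALSE}
# numbered drivers under analysis/ (run from the repository root):
#   01_simulate_session.R       simulate + write the canonical session
#   02_preprocess_qc.R          filter response, task peaks, envelope QC
#   03_synergy_number.R         VAF selection + performance-vs-j sweep
#   04_decoding_performance.R   exhaustive CV, separate vs joint strategies
#   05_grip_force.R             force tracking + grip-induced perturbation
# or the single-shot equivalent:
config <- default_run_config()
run_all(config, out_dir = "results/run1")
```
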