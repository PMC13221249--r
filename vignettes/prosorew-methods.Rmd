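---
title: "Methods: simulating and analyzing feedback-locked EEG in a prosocial reward design"
author: "prosorew"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing feedback-locked EEG in a prosocial reward design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design and what the package computes

`prosorew` implements the complete analysis chain for a feedback-locked EEG
study of reward evaluation under a 2 (beneficiary: self, other) x 2
(magnitude: small, large) x 2 (time: immediate, delayed) within-subject
design: 40 participants, 320 trials (40 per design cell), 62-channel montage
referenced to averaged mastoids, feedback-locked epochs. Every stage is a
pure function of its inputs and a seed, so the whole chain is reproducible at
the table level.

The stages are:

1. **Synthetic cohort generation** (`simulate_cohort`) with a known
   ground-truth effect structure;
2. **Preprocessing** (`reject_artifacts`, `filter_bandpass`,
   `rereference_mastoids`, `baseline_subtract`);
3. **Single-trial ERP scoring** (`score_single_trial`) for the reward
   positivity (RewP, 260--360 ms at Fz/FCz) and P3 (320--420 ms at CPz/Pz),
   plus `grand_average` and `split_half_reliability`;
4. **Time-frequency analysis** (`morlet_transform`, `weld_baseline`,
   `score_band_power`) for theta (4--7 Hz, 150--450 ms, FCz) and delta
   (1--3 Hz, 200--500 ms, CPz) power;
5. **Time-resolved RSA** (`neural_rdm`, `rdm_regression`,
   `cluster_permutation`, `rsa_by_time_condition`);
6. **The statistical layer** (`fit_mixed`, `emm_contrasts`, `rm_anova`,
   `magnitude_effect_correlations`).

# The synthetic-data generator

Each epoch is the sum of:

- **Deflection components** (RewP-like, P3-like): a Gaussian temporal
  template (peak latency / FWHM: 310/100 ms for the RewP at FCz, 370/120 ms
  for the P3 at Pz -- centered inside the corresponding measurement windows)
  multiplied by a Gaussian spatial falloff over the 2-D montage (SD 0.35
  layout units, chosen so the two scoring ROI channels carry more than 80% of
  the peak amplitude). The per-trial amplitude is `X beta_p + e`, where
  `X` is the trial's -0.5/+0.5 coded term vector (intercept, three main
  effects, three two-way interactions, three-way interaction), `beta_p` is
  the participant's coefficient vector (population coefficients plus
  Gaussian between-participant scatter per term), and `e` is trial-level
  Gaussian noise.
- **Oscillatory bursts** (delta at 2 Hz, theta at 5.5 Hz):
  amplitude-modulated sinusoids under a Gaussian envelope with a random
  uniform phase per trial, so they carry single-trial power but largely
  cancel in the average; a phase-locked fraction is configurable. Burst
  amplitudes follow the same coded-coefficient machinery, truncated at zero
  (an oscillation cannot have negative amplitude).
- **Background noise**: 1/f-shaped noise (spectral shaping of a complex
  Gaussian spectrum, exponent 1.0, per-channel SD 8 uV) plus white noise
  (SD 2 uV).
- **Optional artifacts** injected per trial at configurable rates: a step
  (> 50 uV sample-to-sample jump), a large transient (> 200 uV range), a
  flat segment (sample-to-sample differences < 0.5 uV over more than
  100 ms), and a linear drift (> 100 uV across the epoch). Every injected
  artifact is recorded in the ground truth, and the construction guarantees
  the numeric violation is actually present in the emitted trial.

Ratings (the post-experimental liking measure) are generated per design cell
from their own coded coefficients, with between-participant scatter,
Gaussian measurement noise, rounding to integers and clipping to the 1--9
scale.

**Default calibration.** The default effect coefficients follow the
published coefficient pattern for this paradigm: RewP terms
(intercept 5, beneficiary -2.51, magnitude 2.49, time -0.61,
beneficiary x magnitude -1.16, three-way 1.61 uV) and analogous P3 terms;
delta/theta burst amplitudes follow the same qualitative pattern (magnitude
effect stronger for self than other when immediate, comparable when
delayed). Rating coefficients and their between-participant SDs were set so
the expected repeated-measures F statistics match the reported ANOVA
(e.g. a magnitude contrast with mean 1.9 and SD 1.0 rating points gives an
expected F(1,39) near 144). Between-participant SDs for the ERP terms were
chosen so the population t statistics approximate the published ones at
n = 40. Default artifact rates (0.425% per class, 1.7% total) give an
expected retention near 98.3%. These defaults were fixed from the published
statistics before any acceptance run and are conveniences for simulation --
not ground truth about the recorded data.

Note that the coefficients parameterize the component's **peak amplitude**;
a fitted coefficient on the *scored* measure is attenuated by the
measurement geometry -- the mean of the Gaussian template over the scoring
window (about 0.81 for a 100-ms-FWHM component scored over a 100-ms window
centered on its peak) and the spatial falloff averaged over the ROI
channels (about 0.87 for the default spread). Noiseless recovery tests
therefore assert the ground-truth amplitudes exactly, while fitted betas on
scores recover the injected structure up to this fixed, geometry-determined
scale.

**What the generator does not emulate**: ocular or muscle artifact
physiology (ICA removal is out of scope), volume-conducted head-model
topographies (spatial falloff is a schematic Gaussian), non-stationary
background noise, bad channels, or continuous (pre-epoch) recording
structure. Passing recovery tests on this generator demonstrates the
correctness of the analysis chain, not the physiological realism of the
simulation.

# Preprocessing decisions

- **Artifact thresholds are strict inequalities** (a jump of exactly 50 uV
  does not reject), and each rule is evaluated on every channel.
- **Flatline rule**: reject if *any* contiguous 100-ms window on any channel
  has all sample-to-sample absolute differences below 0.5 uV (sliding step
  one sample). The wording "maximum voltage difference < 0.5 uV within
  100 ms intervals" is ambiguous between "some interval" and "all
  intervals"; the "some interval" reading matches the behavior of the
  common ERP toolbox implementations and catches both a dead channel and a
  transient amplifier block.
- **Drift rule**: per-channel least-squares slope over the whole epoch,
  expressed as total change in uV across the epoch; reject when its absolute
  value exceeds 100 uV. The unit of the published "+/-100 uV slope" is
  ambiguous (per second vs per epoch); per-epoch is implemented and the
  threshold is a parameter.
- **Rejection runs before filtering** in the pipeline: the thresholds refer
  to raw voltages, and zero-phase band-pass filtering materially attenuates
  exactly the high-frequency violations (steps) the rules are meant to
  catch.
- **Band-pass filter**: 12 dB/octave roll-off corresponds to an order-2
  Butterworth before the forward-backward pass. The zero-phase response is
  applied in the frequency domain (multiplication by the squared magnitude
  response after reflection padding of 1 s), which equals the ideal
  forward-backward filter without start-up transients; DC is rejected
  exactly, group delay is zero.
- **Baselining** subtracts the mean of a prestimulus window (default
  -200--0 ms) per trial and channel, and refuses to run twice.

# ERP scoring and reliability

Scores are mean amplitudes over the ROI channels and all samples at or
inside the window endpoints (260--360 ms at 500 Hz spans exactly 51
samples). Scoring is linear in the data.

Split-half reliability stratifies the random half-splits by design cell,
correlates the per-participant half means across participants, applies the
Spearman-Brown correction 2r/(1+r), and averages over 100 random splits by
default (the published splitting scheme is not stated; a deterministic
odd/even split is available as an option and agrees closely on simulated
data).

# Time-frequency analysis

The wavelet bank is 30 frequencies geometrically spaced from 1 to 30 Hz with
cycles geometrically spaced 3 to 10 (paired index-wise), so temporal
resolution improves with frequency. Each wavelet is **amplitude-normalized**
(divided by half the envelope sum) so that a unit-amplitude sinusoid at the
wavelet's frequency yields peak power 1 at every frequency. Unit-energy
normalization would make the peak response scale with the square root of
the wavelet duration, which varies across a changing-cycles bank; the
contract worth testing -- frequency-independent power for a fixed-amplitude
oscillation -- selects the amplitude normalization. Epochs are
reflection-padded by the half-support of the lowest-frequency wavelet
(4 sigma_t) before FFT convolution, and the padding is discarded.

**Welding baseline.** All baseline-window power samples (-500 to -300 ms)
from all trials are pooled into one long baseline per channel and frequency;
every sample of every trial is standardized by that pool's mean and SD. The
phrase "z-scored by the average power value" admits a mean-only division
reading; the literal "z-scored" reading (subtract pooled mean, divide pooled
SD) is the default, with `meandiv` and `db` alternatives selectable. The
pooled normalizer is scale-free (invariant to rescaling raw power) and
avoids the bias of per-trial z-scoring, whose per-trial baseline mean and SD
are noisy, skewed quantities for power data; both properties are asserted in
the test suite.

# Time-resolved RSA

Per timepoint, condition-mean topographies over the scalp channels are
compared by Mahalanobis distance, with the channel covariance estimated once
from trial-level residuals (trial minus its cell mean) pooled over all
timepoints and shrunk toward the scaled identity with an analytic
Ledoit-Wolf intensity (the estimator used in the original analysis is not
stated; the shrinkage target and intensity are parameters, and a fixed
covariance can be supplied, which reduces the distances to Euclidean when
the identity is given).

The 28-entry upper triangles of the neural and the three binary model RDMs
are z-scored and the neural vector is regressed on all model vectors jointly
(with an intercept, which is ~0 after z-scoring). Two facts about this
convention deserve emphasis:

- The three factor-difference indicator vectors are **not** orthogonal over
  the upper triangle: excluding the (identically "same") diagonal leaves 16
  ones and 8 pairwise-shared ones among 28 entries, so each pair of model
  vectors correlates at exactly -1/6. The design factors are orthogonal;
  their pairwise-dissimilarity indicators are not. The joint multiple
  regression absorbs this overlap: a neural RDM exactly equal to one model
  yields coefficient 1 for it and 0 for the others, which is the guarantee
  that matters.
- In the **time-split analysis** the cells form a 2x2 design, the RDM is
  4x4 and the regression runs on 6 entries. With so few entries, the
  combination of the distance nonlinearity and the z-scoring of the neural
  vector produces a small positive bias in a predictor's coefficient
  wherever *another* factor's structure is strong, at low trial counts. The
  bias vanishes as cell means stabilize; simulations in the test suite use
  20 trials per full-design cell (40 per split cell), where the split
  analysis cleanly detects an effect injected only in one split level and
  stays null in the other. Studies applying the 4x4 split analysis at much
  lower trial counts should expect this bias.

Cluster-based permutation inference: per timepoint a one-sample t across
participants; contiguous runs with |t| above the two-sided critical value at
the cluster-forming alpha (default .05) form clusters with mass equal to the
sum of t; the null distribution of the maximum |mass| is built from coherent
participant-wise sign flips of the whole series (default 1000); cluster
p = (1 + #{null >= observed}) / (1 + n_perm). The familywise error of this
procedure is verified by simulation to stay at the nominal level.

# The statistical layer

Single-trial scores are modeled with `lme4`: fixed effects are the three
-0.5/+0.5 coded factors and all interactions; the maximal declared random
structure is a by-participant intercept plus slopes for the three factors,
fitted by REML. Under balanced designs with this coding, the fixed-effect
coefficients equal the corresponding cell-mean contrasts, which a
brute-force oracle asserts in the tests.

**Deterministic simplification.** If the maximal fit is singular or does not
converge: drop the random-effect correlations first; then repeatedly drop
the random slope with the smallest estimated variance; then intercept only;
finally a fixed-effects-only OLS fit (which still returns the exact
coefficients for balanced data, including the noiseless limit). The trail is
recorded on the fit object so any simplified model can be matched by
inspection.

**p-values** for fixed effects use a standard-normal reference on t by
default; a Satterthwaite option (via `lmerTest`) is available. Example
p-values are therefore approximation-dependent; coefficient estimates are
not.

**EMM contrasts** are linear combinations of the fixed effects under the
coding -- e.g. the simple magnitude effect in a beneficiary x time cell is
`b_mag + s_b b_bm + s_t b_mt + s_b s_t b_3way` with `s in {-0.5, +0.5}` --
with covariance-propagated SEs, normal-reference p-values, and BH-FDR within
each family (one family per measure). The implementation is cross-checked
against `emmeans` in the tests.

**Ratings** are analyzed by a classical 2x2x2 within-subject ANOVA computed
from per-participant contrast scores; for two-level factors each effect's
F(1, n-1) is the squared paired t, and partial eta squared is
SS_effect / (SS_effect + SS_error). A zero-variance contrast is reported as
infinite F with a degeneracy flag rather than an error. The implementation
is cross-checked against `aov` with participant-crossed error strata.

**Correlation comparison.** Per participant, the magnitude effect
(mean large minus mean small) is computed within each beneficiary x time
cell; Pearson correlations between the self and other effects are computed
separately for immediate and delayed rewards, with one BH-FDR family across
the measures. The two correlations come from the same sample but share no
variables, so they are compared with the ZPF statistic for dependent,
non-overlapping correlations (Fisher z difference scaled by the implied
covariance from the full 4-variable correlation matrix); the test that was
used for the published z values is not named, and a plain independent-samples
Fisher comparison is available as an option. The ZPF null calibration is
verified by simulation.

# Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that keep the full
chain inside desk-scale runtimes while preserving the design structure:
simulations run at 250 Hz (sampling rate is a parameter everywhere; 500 Hz
is the acquisition default), the acceptance cohort is the full 40
participants x 320 trials on the 62-channel montage, unit tests use a
14-channel sublayout and smaller cohorts, and the cluster-permutation
calibration uses 200 replicates of 1000 permutations at 20 participants.
Tolerances follow the quantity: exact identities are asserted to 1e-10 or
tighter; Monte-Carlo quantities carry explicit simulation-error margins.

Degenerate inputs are first-class: all-zero epochs (flatline rejection),
constant power (welding refuses, naming the channel and frequency), double
baselining/normalization (errors), empty clusters (a valid empty result),
zero-variance ANOVA contrasts (flagged), and the noiseless cohort limit
(exact recovery through the OLS fallback).

# Known limitations

- The generator's spatial model is schematic; topography-level inferences
  (e.g. scalp-map comparisons) are out of scope.
- Mahalanobis distances are not cross-validated; distance estimates are
  positively biased under noise (constant bias is absorbed by the RDM
  regression intercept, but the 6-entry split analysis inherits the
  small-sample sensitivity discussed above).
- The EDF+ reader covers the subset of the format needed for event-locked
  epoching (int16 samples, one annotation signal, uniform EEG sampling);
  EEGLAB `.set` (a MATLAB container) is not supported.
- The internal on-disk container stores voltages as float32; metadata
  round-trips exactly, data to single precision.
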