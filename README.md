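# prosorew

Simulation and analysis of feedback-locked EEG in a 2 x 2 x 2 prosocial
reward design.

## The scientific problem

When people earn rewards for themselves versus for another person, neural
reward signals are typically stronger for self-benefiting outcomes — an
*egoism bias*. A key question is whether delaying reward delivery reduces
that bias: if self and other rewards are evaluated more alike when both are
months away, reward deferral becomes a lever for prosociality. Testing this
requires a full single-trial EEG analysis chain over a
beneficiary (self/other) x magnitude (small/large) x time (immediate/delayed)
within-subject design: event-related potential (ERP) amplitudes, oscillatory
power, multivariate representational analyses, and a factorial
mixed-effects statistical layer.

`prosorew` implements that chain as a tested R package driven by a
synthetic-cohort generator with known ground truth, so every stage — and
every inference rule — can be validated without any recorded data. It is
aimed at EEG researchers who want a reproducible, parameter-recoverable
reference implementation of this analysis style.

## What is computed

- **Synthetic cohorts** (`simulate_cohort`): 40 participants x 320 trials by
  default; epochs are sums of Gaussian-templated ERP components (RewP, P3),
  non-phase-locked delta/theta bursts, 1/f + white noise, and optionally
  injected artifacts, with per-trial amplitudes
  `X beta_p + e` under -0.5/+0.5 factorial coding and participant-level
  random effects; liking ratings on a 1–9 scale.
- **Preprocessing**: four artifact rules (step > 50 uV, range > 200 uV,
  flatline < 0.5 uV per 100 ms, drift > 100 uV per epoch; strict
  inequalities), zero-phase order-2 Butterworth band-pass (0.1–35 Hz),
  averaged-mastoid re-reference, prestimulus baseline.
- **Single-trial ERP scores**: RewP = mean 260–360 ms at Fz/FCz;
  P3 = mean 320–420 ms at CPz/Pz; split-half reliability with
  Spearman–Brown correction 2r/(1+r).
- **Time-frequency**: complex Morlet wavelets, 1–30 Hz in 30 log steps with
  cycles 3–10; *welding baseline* normalization — baseline power samples
  (-500 to -300 ms) pooled across all trials into one long reference whose
  mean mu and SD sigma standardize every sample: z = (p - mu) / sigma;
  theta (4–7 Hz, 150–450 ms, FCz) and delta (1–3 Hz, 200–500 ms, CPz)
  scores.
- **Time-resolved RSA**: per timepoint, 8 x 8 neural RDMs of Mahalanobis
  distances d_ij = sqrt((m_i - m_j)' Sigma^-1 (m_i - m_j)) between
  condition-mean topographies (pooled-residual Sigma with Ledoit–Wolf
  shrinkage); z-scored model-RDM multiple regression yields coding time
  series per factor; one-sample cluster-based permutation tests
  (sign-flip null, cluster mass = sum of t) correct across time; the
  analysis repeats within each reward-time level (4 x 4 RDMs).
- **Statistics**: `lme4` mixed models `value ~ ben * mag * tim +
  (1 + ben + mag + tim | participant)` with deterministic simplification on
  singular fits; estimated-marginal-mean contrasts (e.g. the simple
  magnitude effect `b_mag + s_b b_bm + s_t b_mt + s_b s_t b_3way`) with
  covariance-propagated SEs and BH-FDR; 2x2x2 repeated-measures ANOVA with
  partial eta squared; Pearson correlations of self vs other magnitude
  effects by time level, compared with the ZPF statistic for dependent,
  non-overlapping correlations.

See `vignettes/prosorew-methods.Rmd` for the full methods account and the
reasoning behind every tunable default.

## Worked example

```r
library(prosorew)

design <- design_spec(n_participants = 12, n_trials_per_cell = 8,
                      sampling_rate = 250, layout = standard_layout())
cohort <- simulate_cohort(design, default_effects(), default_noise(),
                          master_seed = 42)

scores <- do.call(rbind, lapply(cohort, function(b) {
  e <- rereference_mastoids(filter_bandpass(reject_artifacts(b$epochs)$epochs))
  erp <- baseline_subtract(subset_epochs(e, time_window = c(-200, 1000)),
                           c(-200, 0))
  score_single_trial(erp, default_erp_measures()$rewp)
}))
fit <- fit_mixed(scores)
print(fit)
print(emm_contrasts(fit, "simple_magnitude"), digits = 3)
```

```
mixed model: value ~ ben * mag * tim + (1 + ben + mag || participant)
simplification trail: dropped: value ~ ben * mag * tim + (1 + ben + mag + tim | participant);
  dropped: value ~ ben * mag * tim + (1 + ben + mag + tim || participant);
  dropped random slope: tim
         term estimate    se      t        p
1 (Intercept)    3.595 0.362  9.945 2.66e-23
2         ben   -0.618 0.572 -1.082 2.79e-01
3         mag    2.088 0.534  3.910 9.24e-05
4         tim   -0.636 0.515 -1.236 2.17e-01
5     ben:mag   -1.659 1.030 -1.610 1.07e-01
6     ben:tim   -0.589 1.030 -0.572 5.68e-01
7     mag:tim    0.317 1.030  0.308 7.58e-01
8 ben:mag:tim   -0.666 2.060 -0.323 7.46e-01
                                              contrast estimate   se    z       p   p_fdr
1  magnitude effect | beneficiary=self, time=immediate     2.59 1.04 2.49 0.01260 0.02521
2    magnitude effect | beneficiary=self, time=delayed     3.24 1.04 3.13 0.00175 0.00702
3 magnitude effect | beneficiary=other, time=immediate     1.27 1.05 1.21 0.22785 0.22785
4   magnitude effect | beneficiary=other, time=delayed     1.25 1.03 1.21 0.22634 0.22785
```

The simplification trail shows the maximal random structure was singular at
this small n and was reduced deterministically. The fitted `mag`
coefficient (2.09 +/- 0.53 uV) recovers the injected population peak
amplitude (2.49 uV) times the fixed measurement-geometry attenuation
(window-mean x ROI spatial falloff, about 0.70; see the vignette) within
one standard error. The negative `ben:mag` term and the simple-effect table
carry the injected egoism-bias structure: the magnitude effect is reliable
in self-benefiting cells and about half the size in other-benefiting cells,
FDR-adjusted within the family. (At n = 12 the three-way interaction is
individually noisy, as its SE shows; the acceptance run at n = 40 pins it
down.)

The numbered drivers under `analysis/` run the same chain as a narrative
workflow (simulate, preprocess, ERP scores, TF scores, RSA, statistics),
writing tables under `results/` and regenerable epoch containers under
`scratch/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_preprocess.R && \
Rscript analysis/03_erp_scores.R && Rscript analysis/04_tfr_scores.R && \
Rscript analysis/05_rsa.R && Rscript analysis/06_stats.R
```

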