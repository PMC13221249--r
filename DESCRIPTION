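Package: prosorew
Title: Simulation and Analysis of Feedback-Locked EEG in a Prosocial Reward Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for feedback-locked EEG studies of prosocial reward
    evaluation under a 2x2x2 (beneficiary x magnitude x time) within-subject design.
    Provides a synthetic-cohort generator with known ground-truth effect structure
    (ERP deflections, delta/theta bursts, 1/f background, injected artifacts),
    epoch preprocessing (Butterworth band-pass, mastoid re-reference, four-rule
    artifact rejection, baseline subtraction), single-trial RewP/P3 mean-amplitude
    scoring with split-half reliability, Morlet time-frequency decomposition with
    welding-baseline normalization, time-resolved representational similarity
    analysis with Mahalanobis-distance RDMs and cluster-based permutation
    inference, and the factorial statistical layer (coded mixed-effects models
    with deterministic random-structure simplification, estimated-marginal-mean
    contrasts with FDR, repeated-measures ANOVA, and dependent-correlation
    comparisons).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
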