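Package: cardiofuse
Title: Multimodal Heart-Sound and ECG-Image Screening with Stacked Ensembles
Version: 0.1.0
Authors@R: person("cardiofuse", "developers", role = c("aut", "cre"),
    email = "cardiofuse@example.org")
Description: Desk-scale re-implementation of a multimodal cardiac screening
    pipeline. Phonocardiograms recorded at three auscultation sites are turned
    into log-Mel spectrograms, scanned 12-lead electrocardiogram pages are
    cropped into lead-group views, and a small convolutional network scores
    each modality for severe aortic stenosis, severe mitral regurgitation, or
    left-ventricular dysfunction. Per-modality anomaly probabilities are fused
    by random-forest and gradient-boosted-tree meta-learners over four stacking
    patterns, compared by bootstrap resampling with ANOVA and Tukey-Kramer
    post-hoc tests, and dissected by repeated-seed modality-contribution
    analysis. A disease-conditioned synthetic cohort generator (WAV audio and
    PNG page renders) makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
SystemRequirements: zlib
RoxygenNote: 7.3.3
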