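---
title: "Multimodal cardiac screening with cardiofuse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal cardiac screening with cardiofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Severe aortic stenosis (AS), severe mitral regurgitation (MR) and
left-ventricular dysfunction (LVD, ejection fraction at or below 40%) are
usually confirmed by echocardiography, which is not available in every
clinic. Two ubiquitous bedside sensors carry partial information about all
three: auscultation (heart sounds recorded at the second right sternal
border, Erb's point and the apex) and the printed 12-lead ECG. `cardiofuse`
implements a screening pipeline that trains one small convolutional
classifier per sensor channel and fuses the resulting per-patient anomaly
probabilities with tree-ensemble meta-learners, then asks two statistical
questions: which fused or single-channel model is best (bootstrap + ANOVA +
Tukey–Kramer), and which modality carries the signal (repeated-seed
importance analysis).

Real patient data for this task cannot be shared, so the package ships a
disease-conditioned synthetic cohort generator; every stage of the pipeline
is exercised and tested against it.

## The pipeline

1. **Phonocardiogram frontend.** Each 15-s, 4000-Hz recording is cut into
   4-s windows whose number depends on the severity grade of the active
   disease (3 for non-severe grades; 20/44/42 for severe AS/MR/LVD), with
   start times evenly spaced over the feasible range — heavier oversampling
   simply means more overlap. Each window becomes a log-Mel spectrogram:
   non-centered STFT (Hann window, 512 samples, hop 64), 128 triangular Mel
   filters from 0 Hz to Nyquist (HTK Mel scale), then `log(x + 1e-6)`. The
   non-centered framing convention is deliberate: it is the only one under
   which 4 s × 4000 Hz with 512/64 gives exactly 243 frames, the input shape
   the classifier expects. Amplitudes are intentionally not normalized.
   SpecAugment (2 frequency + 2 time masks, filled with the grid mean) and
   mixup (Beta(0.2, 0.2)) run on the training path only.

2. **ECG frontend.** Pages are 3187 × 1840 grayscale scans; the upper half
   carries the six limb leads, the lower half the six precordial leads.
   Three views are cropped and bilinearly resized: the full-height
   1840-square (all 12 leads, to 512 × 512) and 960-squares from the upper
   and lower halves (to 256 × 256). The limb crop is anchored to the top
   edge and the precordial crop to the bottom edge — a 960-px square whose
   top edge lies at or below row 920 cannot fit on an 1840-row page, so
   bottom anchoring is the only geometry that keeps the crop inside the
   page while centring it in the precordial half. Augmentation shifts the
   crop window horizontally (31 px per step for the 12-lead view, 51 px for
   the half views — chosen so the largest severity factor, ×44, always fits
   on the page), producing the same per-grade counts as the PCG
   oversampling.

3. **Classifier.** One architecture for all channels: ten 3×3 convolution
   blocks with ReLU, batch normalization in blocks 1 and 10 only, 2×2
   max-pooling after blocks 4, 6, 9 and 10 (16-fold spatial reduction per
   axis), global average pooling and a 2-way softmax. Published details end
   there, so channel widths are configurable (default 16, doubling after
   each pooled block; a narrow 4/6/8 "tiny" profile for CPU runs), training
   is Adam at 1e-3 on cross-entropy with soft labels (mixup-compatible),
   and the checkpoint with the best development-split AUC is kept. A
   record's score is the mean positive-class probability over its
   deterministic evaluation segments (the grade-"none" segmentation for
   sounds; the unshifted crop for ECG views).

4. **Stacking.** Four patterns over the six sources (3 sounds + limb +
   precordial; 3 sounds + 12-lead; 3 sounds; limb + precordial), each fit
   with a random forest and with gradient-boosted trees — 8 stacking fits
   per fold, 14 evaluated variants with the 6 single-channel models. The
   meta-learner is trained on the development split's record probabilities
   and its hyperparameters are grid-searched to maximize F1 at a 0.5 cut on
   that same split; no second holdout is described in the reference
   procedure, and the shared test set stays untouched until evaluation.
   Grids (forest: 100/300 trees × depth 3/5/unlimited; boosted: 100/300
   rounds × depth 2/3 × learning rate 0.1/0.3) are package defaults — none
   are published — and ties resolve to the first grid row.

5. **Statistics.** AUC is the tie-aware rank statistic. Metrics are
   bootstrapped by resampling patients with replacement (default B = 2000;
   degenerate single-class resamples are redrawn), reported as mean ± SD.
   Model comparison runs one-way ANOVA over the bootstrapped AUC vectors
   with Tukey–Kramer post-hoc pairs at α = 0.05. Note this mirrors the
   reference analysis: the resamples of one model are not independent
   draws, so the ANOVA is a fidelity choice, not a fresh-sample design; a
   simulation test nevertheless confirms the pairwise false-positive rate
   stays at the nominal level under the global null, because independent
   resampling streams make the per-model bootstrap vectors exchangeable.
   Selection keeps, for each of the 14 methods, its best fold by test AUC
   and ranks the survivors (ties: mean F1, then documented method order).

6. **Contribution analysis.** For a selected stacking model the
   meta-learner is refit 50 times under consecutive seeds with the CNN
   features held fixed; normalized importances (mean impurity decrease for
   the forest, total gain for the boosted learner) are reported as
   mean ± SD per source. Refitting the CNNs as well would cost a full
   training run per repetition and per source; the reference description
   ("an identical model" retrained with fluctuating seeds) is ambiguous on
   this point, and the fixed-feature reading is the one that is
   desk-computable. The boosted learner uses no subsampling by default and
   is therefore seed-deterministic — its contribution SDs are exactly zero,
   which the tests assert rather than hide.

## Cross-validation structure

The "modified" stratified 4-fold scheme keeps one test set common to all
folds (default 20% of patients) and partitions the remainder into four
disjoint development blocks; fold *k* trains on the three blocks not used
as its development set. "Without overlap" is read as applying to the
development blocks — with four groups drawn from a shared pool,
non-overlapping training sets are impossible, so this is the only
consistent reading. Sampling is stratified on the joint grade key of the
three diseases with a global round-robin cursor, and an optional tolerance
check rejects assignments whose per-split severe shares drift from the
cohort's.

## The synthetic cohort: what it emulates, and what it does not

Heart sounds are S1/S2 Gaussian-windowed tone bursts (50–150 Hz
fundamentals, heart rate drawn uniformly from 60–100 bpm) over broadband
noise. Severe AS adds a mid-systolic crescendo–decrescendo band-passed
noise burst (100–400 Hz) loudest at 2RSB, attenuated at Erb, most at the
apex; severe MR adds a holosystolic burst (60–300 Hz) loudest at the apex;
severe LVD attenuates S1 by 1/(1 + effect). ECG pages render
sum-of-Gaussians PQRST templates on a calibration grid without
anti-aliasing; severe AS raises precordial R amplitude, severe MR makes RR
intervals irregular and flattens P waves, severe LVD widens the QRS and
lowers R. All disease terms scale linearly with an `effect_size` that can
be set per modality (`list(pcg = , ecg = )`), which is how the tests plant
signal in exactly one modality. Every random draw is consumed whether or
not a disease is active, so `effect_size = 0` reproduces the healthy
record bit for bit — the determinism contracts are tested at that level.

Default grade prevalences follow the published screening cohort for AS
(785/68/66/132 of 1051) and MR (469/385/130/67); LVD grades are not
tabulated there and default to 78/8/6/8%. The generator emits ground-truth
metadata (systolic windows, QRS widths, RR intervals) so property tests
need no signal-detection stage.

What a green test does **not** establish: the generator is not a
hemodynamic simulation — murmur spectra, lead morphology and noise are
stylized, non-severe grades carry no acoustic signature at all, and
separability is planted by construction. Green means the pipeline's
machinery (shapes, determinism, learning dynamics, fusion and statistics)
behaves correctly, not that clinical performance is reproduced.

## Compute profiles and numerical choices

The `"paper"` profile uses the full input geometry (243 × 128, 512², 256²)
and is not run by the test suite on one CPU. The `"tiny"` profile keeps the
pipeline identical but coarsens resolutions: hop 448 with 32 Mel filters
(35 × 32 grids; hop 512 would violate the `fft_window > hop` invariant),
1/8-scale pages (398 × 230) with proportionally scaled crop geometry, the
narrow channel profile and 3 epochs (2 in the heaviest acceptance loop,
purely for runtime — the measured contribution margins are ~0.95 vs ~0.05,
far from the decision boundary).

Other numerical choices: He-normal initialization from the configured
seed; batch-norm epsilon 1e-5, momentum 0.1, evaluation uses running
statistics; the SpecAugment fill is the grid mean (avoids injecting the
log-floor sentinel); forest `mtry` is `floor(sqrt(d))`; boosted trees use
lambda = 1 and second-order leaf weights; split ties in both learners go to
the lowest feature index and midpoint thresholds; AUC uses average ranks
(ties count half). All seeds derive from a single experiment seed and stay
below 2^31.

## Known limitations

- Single-channel grayscale pages only; no skew, scanning artefacts or
  waveform digitization.
- Non-severe grades are acoustically silent in the generator, so the
  pipeline cannot be exercised on ordinal-severity gradations.
- The boosted meta-learner's deterministic importances make its
  contribution SDs vacuous (zero) unless subsampling is enabled.
- The bootstrap/ANOVA layer inherits the reference procedure's dependence
  structure; its p-values describe that procedure, not an independent
  replication design.
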