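---
title: "Methods: automated full-field ERG phenotyping and variant severity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated full-field ERG phenotyping and variant severity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`fferg` implements an end-to-end analysis of ISCEV-standard full-field
electroretinograms (ERGs) in biallelic *ABCA4* retinopathy (Stargardt
disease):

1. **Signal**: per-repeat preprocessing, automated repeat selection, and
   measurement of the DA 10 and LA 3 a-/b-waves and the LA 30 Hz flicker
   peak.
2. **Phenotype classification**: a hierarchical soft-voting ensemble
   predicting the three functional groups — group 1, dysfunction confined to
   the macula (normal full-field ERGs); group 2, additional generalized cone
   dysfunction; group 3, additional cone *and* rod dysfunction — evaluated by
   repeated nested five-fold cross-validation, in 3-class and binary
   (restricted vs generalized) modes.
3. **Variant severity**: elastic-net regression from allele counts (plus
   age, sex, pupil class) to z-scored component amplitudes; the standardized
   coefficient per variant is its severity score (higher = milder).
4. **Descriptive metrics**: prevalence, eye accounting, interocular
   symmetry, age trends, confusion-matrix summaries.
5. **Synthetic cohorts**: because the clinical dataset this pipeline targets
   is not publicly available, a generator with full ground truth stands in
   for it, making every stage testable.

# Signal pipeline

Each repeat is linearly interpolated onto the 0–80 ms grid at 0.5 ms
(161 samples) and baseline-shifted by the mean of the five samples directly
after time zero (0.5–2.5 ms); the correction is idempotent. For the flash
stimuli the three most mutually consistent repeats are selected by
exhaustively minimizing the summed pairwise mean-squared differences over
all C(n, 3) triples (ties to earliest repeats; two repeats are kept with a
quality flag). We deliberately minimize *within-triple* MSE rather than
distance to a grand mean: the criterion is internal to the candidate
triple, so a majority of artifact-free repeats wins even when artifacts
drag the grand mean. For the 30 Hz flicker, the three repeats with the
largest 30 Hz discrete-Fourier magnitude over the full window (2.4 cycles,
no taper) are selected — this criterion is blind to slow artifacts, a
genuine weakness discussed under limitations.

Component detection low-pass filters the trace with an order-5 Butterworth
filter applied forward–backward (zero phase, so filter delay cannot bias
peak times; the filter is designed in-package from the analog prototype via
the bilinear transform and was verified against an independent DSP
implementation). Extrema are the earliest zero crossings of the first
derivative (central differences) of the filtered trace, subject to
minimum-time cutoffs that suppress artifactual early deflections: a-wave
8 ms, b-wave 20 ms, flicker trough 5 ms. The crossing is localized at the
sample whose derivative is nearest zero. Amplitudes are read from the
**unfiltered** trace at the detected times — a-wave baseline-to-trough,
b-wave trough-to-peak, flicker preceding-trough-to-peak. Filtered reads
would be quieter but attenuate narrow (~2 ms) lobes by far more than the
2% accuracy the noiseless-recovery property demands, so the unfiltered
convention wins.

**Cutoffs.** The defaults are 55 Hz (DA 10), 100 Hz (LA 3) and 60 Hz
(LA 30 Hz), all exposed in `default_config()`. These were re-decided
empirically: below ~80 Hz the small sharp LA 3 a-lobe is smeared out of the
filtered detection trace entirely, while leaving the flicker cutoff high
(100 Hz) lets derivative noise spawn false first-crossings in low-amplitude
recordings, detaching the trough/peak pair from the correct cycle. A
cutoff just above the 30 Hz fundamental makes flicker detection robust;
the amplitude is still read from the unfiltered trace.

Component values are averaged over the selected traces within each eye,
then across available eyes (single-eye patients use that eye alone) — eye
averaging is justified by the high interocular symmetry of inherited
retinal disease.

# Classification

Features are single selected traces: the 161 grid voltages plus age and
binary pupil class (163 numbers). Per stimulus, three base learners are
fitted on single-trace rows and their calibrated class probabilities
averaged (soft vote): an RBF-kernel SVM, boosted decision trees (SAMME),
and ridge-penalized logistic regression. Per-trace votes are averaged
within eye, then across eyes, giving one probability vector per stimulus
per patient; the concatenated 9-vector (6 in binary mode) feeds a final
SVM. This hierarchy tolerates variable repeat counts and single-eye
patients without imputation (a wholly missing stimulus is imputed uniform
and flagged).

Because no SVM or tree library is available in the target environment,
the SVM is a least-squares SVM (one-vs-rest, solved as a regularized
linear system with Platt-style sigmoid calibration fitted on training
decision values) and the trees are an in-package weighted CART-style
learner. Both are deterministic. The soft vote is indifferent to the exact
margin formulation; the LS-SVM keeps the kernel and calibration structure
of the original.

Evaluation is repeated nested cross-validation: outer stratified five-fold
split at the patient level (all traces of a patient stay together); an
inner stratified 80:20 split of each outer-training set (64:16:20 overall)
tunes hyperparameters on validation accuracy only; everything is refitted
on the full outer-training set; metrics come from the untouched outer test
folds, repeated (default 5) with different fold seeds. The standard error
is the SE of the mean over all repeat-by-fold accuracies. Feature
standardization statistics are computed on training rows only. A property
test verifies that permuting held-out labels changes neither fitted
parameters nor test predictions.

Default grids: SVM C ∈ {0.1, 1, 10}, γ ∈ {scale, 0.01}; trees depth ∈
{1, 2}, estimators ∈ {50, 200}; LR C ∈ {0.1, 1, 10}; final SVM C ∈
{0.1, 1, 10}. Class weights (inverse frequency) exist behind a flag, off
by default. The test suite runs reduced grids purely for time.

# Variant severity

Patients contribute allele counts (0/1/2) per panel variant (panel =
variants carried by ≥ 2 patients; rarer alleles pool into an `other`
column), plus age, sex and pupil covariates. Known cis pairs are collapsed
into one complex-allele column; when the two listed variants of a patient
*are* such a pair, the patient has a single recognized allele and is
excluded, exactly like one-variant patients; patients with more than two
listed variants are excluded too. The response — one component amplitude —
is z-scored over retained patients, so coefficients are standardized betas;
predictors deliberately stay on the allele-count scale (a flag enables
predictor standardization for sensitivity analysis).

The elastic net uses mixing 0.5; penalty strength is chosen by internal
5-fold cross-validation on an explicitly supplied log-spaced path
(glmnet's default path stops early when many individually small variant
effects enter slowly, hiding the informative low-penalty region).
Leave-one-out r² refits the model n times at the penalty chosen once on
the full data (re-selecting the penalty inside every LOO fold would be
n-times costlier and changes r² negligibly) and scores the pooled
out-of-sample predictions. Cross-component concordance is the mean
pairwise Pearson correlation of the per-component coefficient vectors;
ranking by mean beta orders variants mild-first.

# The synthetic world

The generator emulates the cohort structure the pipeline assumes, not
retinal biophysics. Waveforms are two Gaussian lobes (flash) or a 30 Hz
fundamental plus 20% second harmonic (flicker); group-1 means are
plausible ISCEV-range values (DA 10: a 250 µV @ 15 ms, b 400 µV @ 48 ms,
widths 4/12 ms; LA 3: a 30 µV @ 15 ms, b 120 µV @ 32 ms, widths 3/7 ms;
flicker 90 µV). The LA 3 widths are narrower than DA 10 by necessity, not
taste: with a 10–12 ms b-lobe at 30 ms, the summed model's derivative never
goes negative near 15 ms and the a-wave trough does not exist, which would
make the stated detection properties unsatisfiable.

Amplitudes decline linearly with age (group-1 rates: DA10 b −1.72, DA10 a
−1.46, LA3 b −0.75, LA3 a −0.20, flicker −0.41 µV/y, reference age 10).
Groups are either sampled directly (default mix 57.6/7.4/35.0%; LA
amplitudes ×0.35 and LA times +6 ms for groups 2–3, DA ×0.35 additionally
for group 3) or driven by genotype: two alleles drawn from a panel with
severities s ∈ [0, 1], LA multiplier 1 − 0.9·min(s)·max(s) — so one mild
allele keeps full-field responses normal — and DA multiplier
1 − 0.9·(min·max)^1.5, encoding cone-before-rod progression (without the
exponent, genotype-driven group 2 could never arise). The expert label is
assigned deterministically from the true patient-level amplitudes against
age-corrected normative limits (the 5th percentile of the group-1
generative distribution conditional on age); an unconditional percentile
would mislabel ~5% of genotype-mild patients.

Eyes share the patient's parameters up to one multiplicative
response-scale factor per eye, whose sd is calibrated so the DA 10 b-wave
interocular correlation equals the target ρ (default 0.95); a shared
factor (rather than independent per-component jitter) reflects that
interocular asymmetry is predominantly global and keeps overlapping-lobe
amplitude reads coherent. Repeats (3–8 per eye) add white noise
(sd 2.5 µV), a slow sinusoidal drift (5 µV), a per-repeat DC offset
(sd 15 µV), and, with probability 0.05, a 300 µV blink transient of 20 ms
Gaussian width (~47 ms FWHM — real blink artifacts are slow events; a
20 ms-FWHM transient would have strong 30 Hz content and the flicker
selection criterion would perversely *prefer* blink traces). Noise and
artifact levels are calibrated once so the world exhibits the interocular
symmetry band (r ≈ 0.90–0.96) it is specified to have, and then frozen.

**What a green test does not establish.** The generator's groups are
cleanly separable by construction (fixed scalings, no overlap continuum),
so classification accuracies here exceed what clinical data supports, and
say nothing about instrument variability, pediatric recordings,
oscillatory potentials, or progressive disease. Genotype effects are
exactly multiplicative and noise is white and Gaussian; real noise is
colored and real severity is not one-dimensional.

# Numerical choices and degenerate inputs

* Resampling is linear interpolation; spans shorter than 0–80 ms are an
  error (no extrapolation).
* Derivative crossings on a tied flat segment resolve to the sample with
  the smallest |derivative|; remaining ties go to the earliest index.
* Undetectable components set a quality flag rather than raising: a flat
  trace is a clinical reality, not a programming error.
* Probabilities are renormalized after every aggregation; Platt outputs
  are clamped to [1e-12, 1 − 1e-12].
* A constant regression response yields all-zero coefficients with a
  warning; constant coefficient vectors are skipped (with a warning) in
  concordance.
* Percentages are rounded half-up to one decimal (base R rounds half to
  even).
* All randomness flows through explicit seeds; identical config + seed
  gives byte-identical metrics JSON.

# Known limitations

* The LA 3 a-wave interocular correlation plateaus near 0.87 in the
  default world: the trough is ~24 µV and the unfiltered two-point
  amplitude read, drift, detection jitter and the calibrated eye factor
  together consume a variance share that caps Pearson r below the 0.9 band
  the four other components reach. (In the clinical cohort this component
  likewise had the lowest interocular r, 0.90.) Reaching 0.9 would require
  an unrealistically quiet world or filtered reads that violate the
  narrow-lobe amplitude accuracy property.
* Noiseless peak recovery within one grid step holds for physiologic lobe
  configurations; an adversarial sharp 2 ms a-lobe riding the rising limb
  of a close, large b-lobe can shift the filtered trough by two grid steps.
* The flicker selection criterion cannot reject slow artifacts, and no
  selection can reject anything when only three repeats exist.
* LOOCV fixes the penalty chosen on the full data (selection bias on r² is
  second-order but nonzero).
* The final SVM consumes eye-averaged probability vectors; per-eye rows
  were a defensible alternative reading and are not implemented.
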