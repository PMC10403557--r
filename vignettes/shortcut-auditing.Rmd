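---
title: "Auditing image datasets for acquisition-dependent shortcuts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing image datasets for acquisition-dependent shortcuts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A binary image classifier trained on a curated clinical dataset can reach
near-perfect internal test performance and still collapse on external data.
A common cause is a *shortcut*: some property of the images that correlates
with the label for reasons unrelated to the task, which the model learns
instead of the intended features. Extrinsic shortcuts (lead markers, text
burn-ins, patient demographics) can be removed by cleaning. Harder are
*intrinsic* shortcuts: global image contrast and sharpness, which depend on
the acquisition system, detector generation, vendor post-processing and
protocol, and which vary from hospital to hospital. If the positive and
negative cohorts of a dataset were acquired under systematically different
conditions, contrast or sharpness alone can separate the classes — and a
deep model will happily exploit that. Because disease features are
*themselves* expressed as contrast and spatial correlation, these shortcuts
cannot be cropped or masked away; they must be detected in the dataset
before any model is trained on it.

## The framework

`adadetect` implements a three-stage audit built entirely from binary
classification and ROC analysis:

1. **Construct** a shortcut training set from disease-free images. A pool
   of images of a single class ("normal") is split uniformly at random into
   two equal halves; one half is labeled 1 and receives a known
   acquisition-dependent perturbation, the other half is labeled 0 and left
   untouched (`build_detective_trainset()`). Because the pool contains no
   class-related content, the *only* signal separating the labels is the
   injected perturbation.
2. **Train and certify** an ensemble "shortcut detective" on that set
   (`shortcut_detective()`, `certify()`). Certification runs two exams on a
   labeled dataset known to be free of the shortcut:
   - *Exam 1*: scored as-is, the detective must sit at chance,
     `|AUC − 0.5| ≤ τ₁`;
   - *Exam 2a / 2b*: with the detective's own perturbation injected into
     the positive / negative class, it must be nearly perfect,
     `AUC ≥ 1 − τ₂` / `AUC ≤ τ₂`. (An AUC of 0 under flipped injection is
     perfect classification; only the label assignment differs.)
   Exam 1 guards against the detective keying on features entangled with
   the audited task; Exam 2 proves it actually detects the perturbation at
   the stated magnitude. All three exams always run, so every report is
   complete.
3. **Scan** a dataset under audit with certified detectives only
   (`scan_dataset()`). Each detective scores the images; if its AUC against
   the dataset's own labels deviates from 0.5 by more than `δ` *and* the
   bootstrap confidence interval excludes 0.5, the corresponding shortcut
   is declared present. Refusing uncertified detectives is the framework's
   central safety contract: a verdict from an unqualified detective is
   meaningless, so `scan_dataset()` errors out before scoring or writing
   anything.

The sole readout everywhere is ROC AUC in the Mann–Whitney form (fraction
of positive–negative pairs ranked correctly, ties counted 0.5) with a
stratified percentile bootstrap CI: positives and negatives are resampled
independently with replacement, preserving both class counts, 2000
replicates by default, 95% interval. Stratification means no replicate can
lose a class, so the degenerate cases behave exactly (perfect separation
gives CI [1, 1]; all-tied scores give [0.5, 0.5]).

## The perturbations

Two single-parameter operator families stand in for the acquisition
attributes:

- **Contrast**: the global power-law (gamma) map
  `p ↦ 255 · (p/255)^γ`, computed in real arithmetic and re-quantized.
  `γ = 1` is the identity; the map is monotone, fixes 0 and 255, and its
  magnitude composes multiplicatively with any baseline gamma already in
  the image.
- **Sharpness**: Gaussian smoothing with scale `σ` (softening), or an
  unsharp mask `p ↦ p + a · (p − G_{σ₀}(p))` with internal scale
  `σ₀ = 1` px (sharpening). The two directions are mutually exclusive in
  one spec.

Default injection magnitudes are `γ = 1.3` and `σ = 1.0` px at 64×64.
They were chosen once as magnitudes comfortably outside the phantom's
baseline acquisition jitter (below) — large enough that a competent scorer
reaches the exam extremes, far smaller than pathology-scale changes — and
are configuration, not constants: an audit should certify detectives at
whatever magnitude it intends to detect.

Numerical choices are pinned so transforms are bit-reproducible:
quantization rounds half-away-from-zero (base R's `round()` rounds half to
even); Gaussian kernels are sampled and normalized with radius `⌈3σ⌉`;
convolution uses symmetric (half-sample) reflection at the boundary;
resizing is exact area-weighted averaging, because resampling itself alters
sharpness and must not vary between runs. One consequence worth knowing:
gamma maps do not commute with 8-bit quantization at the dark end — under
`γ = 2` every pixel below 12 collapses to 0, so an inverse gamma cannot
restore it. Round-trip identities hold to ±1 gray level only where the
forward slope keeps quantization invertible (`p ≥ 64` for `γ = 2`).

## The phantom generator

All tests and the acceptance runs use procedurally generated phantoms
(`phantom_spec()`, `generate_phantom()`): a bright body ellipse on a dark
background, two darker lung ellipses, sinusoidal rib bands across the lung
fields, and additive Gaussian noise. The construction is deliberately the
cheapest one that puts spatial structure at several frequencies into the
image, so that both contrast and sharpness perturbations are learnable.
Two features matter for the audit logic:

- **Baseline acquisition jitter.** Every image — both classes — receives a
  random per-image gamma drawn from `baseline_gamma_range` (default
  [0.9, 1.1]) and a random per-image blur from `baseline_blur_range`
  (default [0, 0.5] px). This emulates natural hospital-to-hospital
  variation and forces a detective to learn the injected *shift* relative
  to that variation rather than an absolute contrast or sharpness value.
  No quantitative survey of real-world spread was available to calibrate
  these ranges; they are free parameters chosen to overlap partially with
  the default injection magnitudes (the composed positive-class gamma range
  [1.17, 1.43] clears the baseline [0.9, 1.1], and the composed smoothing
  scale `√(σ_b² + 1)` ∈ [1, 1.12] px clears [0, 0.5] px).
- **Shortcut-freeness by construction.** `generate_labeled_dataset()`
  assigns labels by a fair coin independent of image content, so every
  image statistic has exchangeable class-conditional distributions — the
  test suite verifies this with permutation tests. These sets play the role
  of the certified shortcut-free exam data.

What the phantom does *not* emulate: anatomy beyond gross ellipses,
pathology, scatter, Poisson noise (the additive Gaussian stand-in is
clipped), detector nonlinearity, or vendor-specific post-processing.
Passing the exams on phantoms therefore demonstrates that the pipeline's
logic and its statistical machinery are correct at the stated magnitudes;
it does not calibrate detection sensitivity on clinical images, which
depends on the real acquisition spread of the audited data.

## The detectives

`shortcut_detective()` trains an ensemble (default five members) on
disjoint validation folds — grouped by patient when patient IDs are
present, so no patient straddles a member's train/validation boundary — and
combines members by the arithmetic mean of their probabilities. Two
backends share this contract:

- `feature_linear` (default): ~19 global image features (intensity
  quantiles, log-quantiles, mean, SD, gradient-magnitude quantiles, log
  gradient and Laplacian energies and their ratio) into a ridge-penalized
  logistic regression (`glmnet`, fixed `λ = 0.01`; the ridge keeps the fit
  finite under the perfect separation these trainsets produce). Seconds per
  detective; this is the backend the test suite and the acceptance runs
  use. It exists because the shortcut signal is global by definition, so
  global features carry all of it.
- `reference_convnet`: a small convolutional network (three 3×3
  conv/ReLU/2×2-average-pool blocks of widths 8/16/32, global average
  pooling, logistic head) trained end-to-end with Adam on the binomial
  deviance, early-stopped on validation AUC. It matches the model class a
  full-scale audit would deploy, at a size that trains in minutes on one
  CPU. Architecture is pluggable and not load-bearing: any competent
  binary scorer certifies against the same exams.

Training is deterministic given the config seed (partitions,
initialization and batch order all derive from it).

## Thresholds and sample sizes

The qualification thresholds are design choices, recorded in every report
and overridable:

- `τ₁ = 0.07`: under the null, the AUC of an n-image balanced exam set has
  standard deviation ≈ `√((n+2)/(3n²/4))` ≈ 0.018 at n = 1000, so 0.07 is
  a ≈4σ band — wide enough that a sound detective essentially never fails
  Exam 1 by chance at that size, tight enough to catch task entanglement.
- `τ₂ = 0.01`: the exams are designed to be easy at the certified
  magnitude; anything short of near-perfection means the detective cannot
  be trusted to flag a real shortcut of that size.
- `δ = 0.10` with a CI-excludes-0.5 requirement: the effect-size guard
  stops trivially significant micro-deviations at large n from being
  called shortcuts, and the significance guard stops large but noisy
  deviations at small n. Both must fire.

Certification exam sets should contain on the order of 1000 images: at a
few hundred, chance-level AUC draws routinely leave the `τ₁` band (the
null sd at n = 400 is ≈0.029) and certification becomes a coin flip. The
package's own test suite certifies on 1000-phantom sets and trains on
600-image pools at 64×64 — sizes chosen so a full certification runs in
well under a minute with the feature backend; the convnet contract test
runs at 32×32 with a two-member ensemble for the same reason.

## Known limitations

- The contrast/sharpness operator families are canonical but not
  exhaustive; vendor post-processing can produce local, adaptive changes
  (frequency-domain MTF shaping, adaptive histogram equalization) that a
  global gamma or Gaussian does not span. The framework extends to any
  parameterized perturbation by writing a new spec type, but each new
  attribute needs its own certified detective.
- A scan verdict is attribute-specific: "no shortcut detected" means the
  certified attributes at the certified magnitudes, nothing more.
- Image-level splitting is the default for trainset construction; when the
  same patient contributes many images, pass patient IDs so folds (and,
  where appropriate, the split) respect them.
- DICOM files are not read directly; extract the pixel array and pass it
  through `window_and_quantize()` with the file's window center/width (or
  the full observed range when absent).
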