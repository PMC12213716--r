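---
title: "Benchmarking super-resolution harmonization of paired low/high-field MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking super-resolution harmonization of paired low/high-field MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldbridge)
```

## The problem

Longitudinal and multi-site neuroimaging studies often mix 1.5T and 3T
T1-weighted scans of the same subjects. The field-strength difference changes
SNR, tissue contrast, and effective resolution, so images cannot be pooled
naively. One harmonization strategy is computational: apply super-resolution
(SR) to the low-field image and ask how close the result comes to the
subject's own high-field scan. `fieldbridge` implements that entire
evaluation loop as a reproducible benchmark on synthetic paired data:

1. **generate** paired high/low-field slice stacks per subject (three vendor
   strata, same-vendor pairs only);
2. **register** each low-field stack rigidly onto its high-field pair;
3. **super-resolve** with five methods — bicubic and Lanczos interpolation,
   ESPCN, SRGAN, and a transformer-CNN hybrid GAN (TCGAN);
4. **score** every result with PSNR, SSIM, a deterministic perceptual
   feature distance, and the thresholded Intensity Differences in Pixels
   (IDP) metric;
5. **evaluate** with the paired design: slice → subject → cohort averaging,
   vendor stratification, two clinical-significance anchors, and pairwise
   paired comparisons with confidence intervals.

## The synthetic cohort

Real paired cohorts are access-restricted, so the package generates
phantoms with the statistical structure the analysis needs — not anatomy.
`make_high_field_subject()` builds nested smooth elliptical regions with
three tissue intensity tiers (CSF ≈ 0.25, gray ≈ 0.55, white ≈ 0.85 on a
[0, 1] scale), a cortical ripple, a few Gaussian "lesions", and a hard-zero
background; radii shrink across slices like an axial sweep through a
spheroid. Every geometric and intensity parameter is drawn from a seeded
per-subject stream, so cohorts are pure functions of their seed.

`degrade_to_low_field()` produces the 1.5T-like member of the pair by, in
order: contrast scaling toward the slice mean (default retention 0.85),
Gaussian blur (FWHM 1.5 px), a multiplicative low-order-polynomial bias
field (peak deviation 0.1, mean-normalized), additive Gaussian noise
(SD 0.03 of the intensity range), a vendor gain (A = 1.0, B = 1.15,
C = 0.9), and a small rigid misalignment (up to ±3 px, ±5°). Noise is
applied as a magnitude reconstruction (`abs(signal + noise)`), which keeps
intensities non-negative and gives the Rayleigh-like positive background of
real magnitude MRI. Neutral parameters reproduce the input bit-for-bit — a
tested invariant.

Two details matter downstream:

* **Repeat scans.** `make_repeat_scan()` regenerates a low-field stack with
  identical deterministic components (same bias field, blur, misalignment)
  but an independent noise draw. Averaging *k* repeats converges at the
  1/√k rate to the folded-normal mean E|v + ε| — not to the noiseless image,
  because magnitude reconstruction is biased upward near zero signal. The
  test suite checks convergence against the analytic folded-normal mean.
* **What the phantom does not model.** No anatomy, no k-space artifacts, no
  through-plane resolution differences, no motion or ringing. Passing tests
  show the *pipeline logic* is correct under a controlled generative model;
  they do not certify performance on real scans.

## Registration

The low-field stack is realigned to its high-field pair with an in-plane
rigid transform (tx, ty, θ) shared by all slices, minimizing mean squared
error on median-scaled, lightly smoothed intensities (FWHM 1 px) with a
coarse-to-fine pyramid (4×, 2×, 1×) and Nelder-Mead at each level.

The objective is **symmetric**: the moving stack is warped by half the
candidate transform and the reference by the inverse half, so both sides
incur exactly one bilinear resampling. This matters: the naive asymmetric
objective (warp only the moving image) is biased toward under-rotation,
because resampling blurs the moving image while the reference stays crisp,
and the MSE rewards skipping part of the rotation. With the symmetric form,
98/100 seeded transforms (|t| ≤ 5 px, |θ| ≤ 10°) are recovered within
0.5 px / 0.5° on noiseless phantoms.

Because rotation landscapes on ring-like anatomy have shallow local minima,
the descent starts from the best few candidates of a coarse transform grid
(θ in 2° steps), and an automated normalized-cross-correlation check
(threshold 0.95, scale-invariant, foreground only) triggers seeded restarts
from perturbed initializations — the automated surrogate for an
inspect-and-repeat realignment loop. One caveat is documented in the tests:
re-registering an already-registered stack is *not* exactly idempotent,
since the twice-resampled stack is blurrier than the reference, which can
shift the rotation optimum by about a degree.

## Super-resolution methods

The pipeline emulates the coarser low-field acquisition matrix by block-mean
downsampling the registered low-field stack by the SR factor (default 2);
each method then maps it back to the high-field grid.

**Interpolation.** Bicubic uses Keys' cubic convolution; the family's free
parameter is fixed at a = −0.5 (Catmull-Rom), the interpolating member, so
linear ramps pass through exactly. Lanczos uses the windowed sinc with
window a = 3 by default. Both are separable, use pixel-center alignment
(scale 1 is the exact identity), replicate edges, and renormalize kernel
weights to sum to one at every output position, so constants — and affine
intensity transforms generally — are preserved exactly.

**Learned methods.** No deep-learning framework is assumed: the three
networks run on a small deterministic neural-network engine written in R
(im2col convolution via BLAS, manual reverse-mode gradients, Adam), with
every layer validated against finite differences in the test suite.

* *ESPCN*: 5×5 and 3×3 convolutions with tanh activations computed in
  low-resolution space, followed by a sub-pixel (pixel-shuffle) head;
  trained on MSE.
* *SRGAN*: residual-block generator with a global skip and pixel-shuffle
  upsampling; convolutional discriminator with leaky-ReLU producing one
  logit; adversarial + L1 + perceptual training.
* *TCGAN*: a transformer generator (8×8 patch embedding, sinusoidal
  positional encoding, two pre-norm attention blocks with two heads) in
  series with a CNN U-Net generator carrying a pixel-shuffle head, judged
  by a *patch-level* discriminator that emits a grid of patch scores rather
  than one scalar. The transformer stage sits on a global residual, and an
  ablation switch proves it is live (outputs change when bypassed).

Desk-scale defaults — base width 16, two residual blocks, transformer depth
2 — keep each model CPU-trainable in seconds to minutes. Training is
per-sample Adam (batch size 1), which is why the networks carry no batch
normalization: its statistics are undefined at batch size one. GAN loss
weights default to adversarial 10⁻³, pixel (L1) 1, perceptual 6×10⁻³. The
perceptual *training* loss uses raw backbone-feature MSE (simple, stable
gradient); the perceptual *metric* (below) unit-normalizes features first.
Scale 1 is supported as a same-grid restoration mode. All weight
initialization and data shuffling derive from the model seed; two runs with
the same seed produce identical weights.

## Metrics

All metrics operate after quantization to 8-bit gray levels
(`round(255·clip(x, 0, 1))`, half away from zero), because the difference
counting below is defined in gray levels and the PSNR peak is 255.

* **PSNR** is provided in two variants: `standard`
  (10·log₁₀(255²/MSE), the canonical definition) and `as_printed`
  (20·log₁₀(255/MSE), a formula that circulates in the applied literature).
  They agree only at MSE = 1; the package surfaces both rather than
  silently correcting either. Identical images return the +∞ sentinel.
* **SSIM** uses the reference constants: 11×11 Gaussian window (σ = 1.5),
  C1 = (0.01·255)², C2 = (0.03·255)², C3 = C2/2, unit exponents, valid-mode
  windows. It is validated against a naive per-window oracle to 10⁻⁷.
* **Perceptual distance** runs both images through a fixed-seed,
  untrained convolutional feature extractor, unit-normalizes each layer's
  features along channels, and averages squared differences across layers.
  Absolute values are *not* comparable to published LPIPS numbers — only
  orderings are meaningful, and only orderings are used.
* **IDP** is the fraction of pixels whose relative difference from the
  reference strictly exceeds a threshold ψ, swept over
  ψ ∈ {0, 10, 20, 25, 50, 75}%. The ratio is undefined at reference 0; the
  default policy counts a nonzero candidate on zero reference as a
  difference at every ψ (hallucinated signal) and a zero-zero pixel as
  agreement, keeping identical-image IDP at exactly 0. A mask policy that
  excludes reference-zero pixels is selectable. At ψ = 0 the metric equals
  the fraction of pixels with at least one gray level of difference, which
  is also what the `difference_overlay()` visualization counts.

## Evaluation design

Slice-level records are averaged per subject, then unweighted across
subjects (overall and per vendor) — so every subject counts equally
regardless of slice count. Two anchors give the numbers context:

1. **Baseline anchor** — the original low-vs-high comparison. A method
   "beats the baseline" only if its index is better with one-sided paired
   significance at α (default 0.001).
2. **Repeat-scan anchor** — the IDP between two same-session low-field
   repeats (default 9 subjects) is the measurement-variability floor.
   Each method's cohort IDP is reported as a signed gap above that floor;
   smaller is better, and values below the floor are flagged rather than
   celebrated.

Pairwise method comparisons use either a paired t-test on subject-level
values (with its analytic 95% CI) or an intercept-only regression on
slice-level differences with subject-clustered robust standard errors and
t critical values on (clusters − 1) degrees of freedom. These are standard,
clearly-labeled procedures — the package does not claim to reproduce any
particular mixed-model or GEE specification. Raw p-values are reported
alongside Holm-adjusted ones. Degenerate cases are defined rather than
left to error: identical arms give p = 1; constant nonzero differences give
a point CI and p = 0; infinite metric values (an exact-copy oracle under
PSNR) yield a sign-only verdict.

The statistical layer is calibrated by simulation in the test suite:
type-I error within [0.02, 0.08] at α = 0.05 over 400 null replicates, and
95% CI coverage of a true shift at or above 93% over 200 replicates.

## Numerical and design choices

* All randomness flows from one global seed through a documented hash
  (`derive_seed()`), so each stage is independently reproducible.
* Ranking ties are broken alphabetically and flagged explicitly.
* The SR scale between the low and high-field grids is configuration
  (default 2); the acquisition-matrix ratio of real paired protocols varies
  by vendor and is not fixed by the benchmark.
* Problem sizes in the tests and the acceptance script (8–13 subjects,
  32–64 px slices, 40–50 training pairs, ≤ 10 epochs) were chosen so the
  full benchmark runs on a single CPU in minutes; they are stated in the
  scripts themselves.
* Cohort size is configurable rather than fixed: published paired cohorts
  report slightly different subject counts per stratum between sources, so
  the generator takes vendor counts as input.

## Limitations

Synthetic phantoms bound what the green test suite can show: it certifies
the metrics, the registration, the training loops, and the statistics — not
harmonization quality on real brains. The learned models are desk-scale and
deliberately small; their numbers are internally comparable but not
comparable to literature values. The perceptual backbone is untrained by
design (determinism over fidelity), and a pretrained backbone can be
plugged in where fidelity to human perception matters.

## A worked run

```{r example, eval = FALSE}
config <- pipeline_config(
  subjects = c(A = 2, B = 1), n_slices = 4, size_px = 64,
  methods = c("bicubic", "lanczos"), metrics = c("psnr", "ssim", "idp"),
  seed = 7)
report <- run_pipeline(config)
report$rankings$idp_psi0
report$anchors$verdicts
```
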