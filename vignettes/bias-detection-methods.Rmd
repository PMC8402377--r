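---
title: "Detecting shortcut learning with saliency methods: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shortcut learning with saliency methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(biaslens)
```

## The problem

Medical-image classifiers can reach high accuracy, F1 and AUC while relying
on *spurious artifacts* — image content correlated with the label but
causally unrelated to the condition. CT-scan collections assembled from many
publications carry exactly this hazard: annotation letters, colored
markings, off-gray hue tints, round reconstruction frames and visible
scanner supports occur with different frequencies in the two classes, so a
network can "succeed" by reading the annotation rather than the lungs.
Softmax outputs cannot reveal this; attribution heatmaps can.

`biaslens` packages that diagnostic workflow end to end: a synthetic
CT-like benchmark whose artifact-class correlations are *known by
construction* (with per-artifact ground-truth masks), seven attribution
methods behind two small classifier contracts, exhaustive softmax-averaging
ensemble search, and a localization score that turns heatmaps into a
quantitative bias verdict.

## The synthetic benchmark

`dataset_spec()` defaults reproduce the composition of the public COVID-CT
collection: 746 images, train/val/test = 425/118/203, with class-0/class-1
counts (234, 191), (58, 60) and (105, 98). Each image is a dark background,
a light elliptical body, two darker lung ellipses, and — for class 1 only —
a bright lesion blob, so an unbiased classifier always has a legitimate
signal to learn. Artifacts are planted independently per image with
class-conditional rates (defaults: letter 0.05/0.60, colored marking
0/0.25, hue tint 0.02/0.10, round frame 0.50/0.50, support structure
0.30/0.70). The real collection publishes no artifact frequencies; these
rates are stand-ins chosen so artifacts correlate with the positive class,
and are configuration, not claims about the original data. Letter glyphs
are sized so the letter mask occupies roughly 1–2% of the pixels,
matching the visual prominence of annotation text in the source imagery.
A per-image multiplicative contrast factor `U(1 ± 0.15)` emulates
heterogeneous acquisition; optional aspect-ratio jitter (off by default)
emulates mixed aspect ratios.

What the generator does *not* emulate: anatomical texture, 3-D consistency
across slices, scanner noise spectra, or the long-tailed variety of real
annotation styles. Passing tests on this benchmark therefore demonstrate
that the *methods* recover planted correlations with ground truth available
— they do not certify behaviour on real CT data.

Determinism: one global stream per dataset seed, with per-image substreams
derived from the image index, so generation is order-independent and any
single image can be re-rendered bit-identically.

## Classifier contracts and oracles

All explainers consume classifiers through a black-box contract (batch of
images → softmax rows) or a differentiable contract that adds class logits,
input gradients and named feature maps with their gradients. Gradient-based
methods differentiate the **pre-softmax logit** of the target class (the
convention of the original class-activation-map literature); perturbation
methods weight by the **softmax probability**. Every heatmap's JSON sidecar
records which target was used.

`make_region_oracle()` is the package's ground-truth instrument: its class-1
logit is `gain ×` the channel-weighted mean intensity over a fixed region,
so every derivative has a closed form, predictions are provably local to the
region, and a 14×14 block-pooled copy of the masked weighted image gives
GradCAM an analytically known layer. Keying the oracle on an artifact mask
manufactures a classifier that is biased *by construction*; keying it on the
lesion manufactures an unbiased one.

`train_small_cnn()` is a compact three-block CNN (3×3 convolutions, 2×2
pooling, global-average-pooled linear head) written directly in R with exact
backpropagated gradients — which is precisely what the gradient explainers
need, and keeps every attribution path testable against finite differences.
Training follows the two-phase transfer-learning recipe: a frozen-features
phase training only the head, then full unfreezing with flip/rotation/
translation/zoom augmentation (±10°, ±10%), checkpointing weights after any
phase-2 epoch whose validation accuracy **strictly exceeds 0.80**. The
desk-scale defaults are 4 + 10 epochs, batch 32, Adam at 1e-2/3e-3, on
32×32 renderings of the 746-image benchmark (about a minute of CPU); the
original full-scale experiment trained 30 frozen epochs and a long
checkpointed phase reported inconsistently as 200 and as 1000 epochs — both
figures are recorded in the documentation, neither adopted. Validation
accuracy on the synthetic benchmark typically lands between 0.6 and 0.9
depending on the seed, comfortably above the 60/118 ≈ 0.508 majority rate.

## The seven attribution methods

* **LIME** (`lime_explain`): SLIC superpixels (k-means in CIELAB + xy;
  default request `nslic = 15`, the heuristic that separates lungs from
  background), uniform binary on/off perturbations plus the all-on vector,
  off segments replaced by the *image mean color* (a black fill would plant
  a fake dark artifact on CT backgrounds — note the flip side: on a
  uniform image the mean fill is a no-op, so tests of constant images use a
  black baseline), cosine-distance exponential kernel of width 0.25, ridge
  surrogate with penalty 1.0 and a documented penalty→0 mode that makes the
  fit exactly weighted least squares for oracle validation.
* **Squaregrid** (`squaregrid_explain`): LIME run over centred power-of-two
  grids (default levels 1–5, i.e. 2×2 … 32×32 cells; residual offsets fall
  at the edges, where cells absorb the remainder), with per-level maps
  **summed without normalization** — the literal reading of the method.
* **RISE** (`rise_explain`): `H = 1/(N p1) Σ f(I⊙Mᵢ) Mᵢ` with masks drawn as
  s×s Bernoulli(p1) grids, bilinearly upsampled to a canvas one cell larger
  than the image and cropped at a random within-cell offset (defaults
  N = 4000, s = 7, p1 = 0.5). All mask randomness is drawn up front so
  results are invariant to the classifier-call batch size.
* **GradCAM** (`gradcam`): α-weights as the global average pool of
  ∂logit/∂feature-map, rectified α-weighted sum, bilinear upsampling, then
  division by the maximum when positive (values in [0, 1]). Undefined for
  ensembles — an averaged softmax has no single internal layer — and the
  package refuses with exactly that diagnosis.
* **Vanilla / Smooth / Integrated Gradients** (`vanilla_gradient`,
  `smooth_gradient`, `integrated_gradient`): channel-max absolute input
  gradient; its mean over 25 Gaussian-noise replicas (σ = 0.15 intensity
  units, noisy images deliberately not re-clipped); and the midpoint-rule
  path integral from a black baseline (default 50 steps, inside the 20–300
  band that makes the completeness identity hold to ≲1%), channel-summed
  and signed.

Scale conventions are part of the heatmap type: `symmetric_signed` (LIME,
Squaregrid, IG), `min_max` (RISE — absolute values carry no meaning),
`unit` (GradCAM), `magnitude` (Vanilla/Smooth). Rendering and scoring both
key off the convention.

## Ensemble search

`enumerate_ensembles()` scores every nonempty subset of a model pool from
cached per-model validation probabilities — the simple average is exactly
what re-inference would produce, by the purity contract, so all 2¹⁴ − 1 =
16,383 ensembles of a 14-model pool take seconds. `select_best()` picks
maximal validation accuracy, then fewest members. Because exact
equal-accuracy equal-size ties do occur at this scale, a third deterministic
level — lexicographically smallest member set — replaces the original
practice of picking a tied ensemble at random; this deviation is deliberate
and makes selection reproducible. Test metrics are carried for reporting
only and never consulted during selection.

## Localization scoring

`localization_score()` reduces a heatmap and a binary region to
`mass_fraction` (share of relevance inside the region; relevance is the
positive part for signed/unit maps, absolute value for magnitude maps,
min-shifted values for RISE), `area_fraction`, and their ratio
**enrichment** — the headline number, because raw mass conflates artifact
size with attention and needs no threshold. Enrichment > 1 means
disproportionate focus. The quantitative operationalization of "the model
focuses on the artifact" via enrichment is this package's own; the source
analysis made the corresponding claim qualitatively from heatmap panels.

`compare_report()` assembles the per-model × per-technique grid with both
renderings per cell (colormapped map; underlay with the top-decile region
outlined) and a CSV of every (classifier, technique, artifact) score.
Per-cell failures are recorded, never fatal; GradCAM × ensemble cells are
marked "undefined for ensembles".

## Numerical choices and degenerate inputs

* Ridge system solved with an unpenalised intercept; penalty→0 uses a QR
  fall-back. Exhaustive perturbation mode caps at 16 segments.
* SLIC: 10 k-means iterations, compactness 10, connectivity enforced by
  component relabelling with fragments under a quarter of the mean segment
  size merged into their dominant neighbour; a constant image returns one
  flagged segment with a warning. Labels are 1-based.
* Bilinear resizing uses half-pixel centers with clamped edges; RISE's
  upsampling uses a two-stage lerp that is exact for constant grids (p1 = 1
  gives masks identically 1).
* Max-pool backprop breaks ties by first-match in a fixed scan order;
  `tanh`/average-pool variants provide an everywhere-smooth model where
  numerical identities (IG completeness) are checked.
* Zero-relevance heatmaps score `mass_fraction = 0`; all-zero masks are
  rejected.
* F1 is the positive-class binary F1 with 0/0 defined as 0; AUC is the
  tie-aware rank statistic and is reported `NA` on single-class splits.

## Problem sizes used by the test suite

Unit oracles run at 12–28 px; the planted-bias recovery experiment runs at
80×80 px with LIME (400 samples), Squaregrid (levels 2–3, 300
samples/level), RISE (N = 4000) and IG (50 steps), five seeds per oracle;
the training check uses the full 746-image composition at 32×32. These
sizes are the package's chosen desk-scale study conditions.

## Known limitations

* **RISE and mass-based scores.** The RISE estimator's expectation is
  `E[f]` at *every* pixel (a flat pedestal) plus a localized covariance
  bump at least one upsampled cell wide. Min-shifting removes the pedestal
  only up to Monte-Carlo noise (~3σ per pixel, σ ∝ 1/√N), so mass-based
  enrichment of a small artifact saturates around 2–6 at practical N even
  when the argmax localizes perfectly — RISE reliably *ranks* its own
  region above the alternative (the discrimination inequality holds on
  every seed tested) but does not reach the ~5× mass concentration that
  segment-sharp methods (LIME, Squaregrid) or pixel-sharp methods (IG)
  attain easily. Argmax-style checks are the appropriate localization test
  for RISE.
* The hand-written CNN is desk-scale: it demonstrates the mechanism
  (two-phase training, checkpoint policy, gradient attribution), not the
  architecture comparisons of full-size pretrained networks.
* The hue-tint artifact is global, so its mask is the whole frame and
  overlaps all other masks by construction; letter and marking masks are
  guaranteed disjoint.
* SLIC segment counts are a target, not a contract; degenerate images
  collapse to fewer segments.
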