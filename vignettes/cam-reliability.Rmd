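---
title: "Measuring CAM reliability on soft-boundary tissue damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CAM reliability on soft-boundary tissue damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Class activation maps (CAMs) locate the image regions a CNN classifier
finds discriminative, and weakly supervised segmentation pipelines use them
as stand-ins for pixel annotations. Their reliability is usually judged on
objects with crisp boundaries. Freeze–thaw damage in muscle tissue imaged
by MRI is the opposite case: the "object" is a gradual texture
transformation with no defensible pixel-level boundary, annotators
disagree, and an external reference exists only in aggregate (the liquid a
sample loses after thawing, a proxy for cell rupture). `camrel` rebuilds
that evaluation setting synthetically, so that every stage — classifier,
CAM, threshold, agreement statistic — can be scored against exact ground
truth, and implements the agreement statistics used to compare CAM methods
and CNN models on equal terms.

## The synthetic study

`generator_config()` + `generate_dataset()` emulate a three-group freezing
experiment. Defaults are the study conditions: groups of 11/11/10 samples
(32 total) at severities 0.9/0.5/0.1 — slow freezing damages most — with 8
slices per sample at 64×64 pixels, 12-bit quantized intensities.

Per sample:

* an elliptical tissue **foreground** (axes ≈ 0.26–0.42 of the image side,
  random orientation, slight per-slice girth jitter) on a dark background
  (0.06 vs 0.55 mean tissue intensity);
* a shared smooth **base texture** (Gaussian random field, correlation
  length 4 px, amplitude 0.10) — the *same* texture in the fresh and the
  damaged stack, so sample identity carries no class signal;
* a **damage field**: a standardized Gaussian random field with correlation
  length `damage_field_smoothness` (default 9 px) plus a radial centre-bias
  term `center_bias · (1 − ρ²)` (default weight 1.5), reflecting that
  freeze damage concentrates where phase transitions linger — the slice
  centre. The **truth mask** thresholds this field at the quantile that
  realises the slice's target damage fraction; because the field is smooth,
  the mask boundary is soft by construction;
* the **damaged slices** are the fresh slices plus a perturbation
  `severity · taper · (0.20 + 0.30 · texture)` inside the mask, where
  `texture` is a finer random field (correlation length 2.5 px). The taper
  is 1 over the mask interior and falls to 0 across the outer ~30% of the
  within-mask field range. Full interior amplitude matters: if the
  perturbation decayed across the whole mask, the truth mask would claim
  damage where the image is pixel-identical to fresh and no image-driven
  method could be scored against it. Both stacks receive independent
  acquisition noise (s.d. 0.01) and optional 12-bit quantization;
* the **target damage fraction** per slice is `severity · (B + ε)` with a
  per-sample `B ~ Beta(6, 3)` (between-sample biological variability,
  mean ≈ 0.67) and per-slice jitter `ε ~ N(0, 0.05)`, capped at 0.95;
* **liquid loss** is `2 + 20 · damage_fraction + N(0, 1.5)` percent,
  clipped to [0, 100] (`simulate_liquid_loss()`); a ~2% baseline drip and a
  realistic 2–22% range. `liquid_loss_percent(m0, mL)` computes the
  measured quantity `100 (m0 − mL)/m0` from masses.

The generator emulates the *statistical* structure of such a study —
paired stacks, soft boundaries, hierarchical sampling, an external damage
proxy — not MRI physics: there is no bias field, no vacuum-pack artifact,
no T2 contrast model, and the damage field's spatial statistics are free
knobs rather than calibrated to real tissue. Passing tests therefore show
the *pipeline* is correct and self-consistent, not that a particular CAM
method would reach the same numbers on clinical data.

## Preprocessing

`foreground_mask()` follows the classic artifact-suppression recipe:
convert to 8-bit, max filter, erosion, light Gaussian blur, then k-means
(k = 2) on intensities, labelling the higher-mean cluster as foreground.
Defaults are 7×7 structuring elements — equal max/erode sizes form a
grayscale closing that fills dark texture holes without displacing the
boundary — and σ = 0.5; on noiseless generator slices this recovers the
true foreground to ≥ 99% pixel agreement (the test suite pins this).
k-means is initialised deterministically from the two intensity extremes,
so there is no clustering randomness to seed; labelling by cluster *mean*
(not index) makes the mask invariant to any relabelling. A constant image
has no two clusters and raises an error.

`augment()` emits independent copies per transform (the composition order
is deliberately not stacked): one random rotation in ±45°, horizontal and
vertical flips, one random shift up to ±20% per axis (zero fill, matching
background-removed images), and three contrast variants (2–98% percentile
stretching, histogram equalization, CLAHE). Labels and sample identity are
preserved. `split_by_sample()` assigns whole samples to train/val/test
(default 80/10/10, largest-remainder rounding, ≥ 1 sample each), the
standard guard against slice-level leakage in MRI-style data.

## Classifier backend

Full-scale studies use ImageNet backbones; what the CAM methods actually
consume is much narrower — pre-softmax scores `Y^(c)`, activations `A_k`
at a named layer, and gradients `∂Y^(c)/∂A_k(i,j)`. `cam_cnn()` provides
three desk-scale families (~10³–10⁴ parameters) that preserve the
architectural distinctions the cross-model comparison needs: `"plain"`
(sequential conv/pool stack), `"residual"` (identity-skip block), and
`"inception"` (parallel 1×1/3×3 branches). All end in global average
pooling and a linear head, trained from scratch. The engine is written in
the package (conv kernels in C++/Armadillo) because the CAM methods need
gradients w.r.t. *activations*, which off-the-shelf R model fitters do not
expose; `class_gradient()` is verified against central finite differences
in the test suite.

Training (`cnn_train()`) is mini-batch SGD on softmax cross-entropy:
batch 32, learning rate 0.02, classical momentum 0.9, at most 60 epochs
with early stopping after 15 epochs without validation improvement
(best-validation weights are restored). Full-scale protocols in this
setting train thousands of epochs at learning rate 5·10⁻³; at a desk-scale
epoch budget that step size verifiably undertrains, so the default
compensates with a moderately larger step, momentum, and a fixed input
transform mapping [0, 1] intensities to [−1, 1] at the network entry
(`center = 0.5, scale = 2`; disable for hand-built toy nets). Training is
deterministic given the seed under single-threaded BLAS. "Validation error
did not increase" in early-stopping descriptions is read as "did not
improve", the standard semantics.

## The CAM methods, as implemented

All methods target the pre-softmax score of the damaged class (`y = 1`;
fresh-class maps are not computed) at the deepest spatial layer unless
stated, and share one post-processing: ReLU, bilinear upsampling to input
resolution, min–max normalization to [0, 1] (an identically-zero raw map
stays zero; a non-zero map always attains 1). Uniform post-processing is
what makes cross-method IoUs well defined. Row/column index conventions
are internal; all statistics are index-symmetric.

* **Grad-CAM** — `w_k = mean_{ij} ∂Y^(c)/∂A_k(i,j)`, map
  `ReLU(Σ_k w_k A_k)`. On a GAP + linear architecture this reduces exactly
  to the original CAM weight projection (tested to 1e-6).
* **Grad-CAM++** — `w_k = Σ_{ij} α_k(i,j) · ReLU(∂Y^(c)/∂A_k(i,j))`. The
  α coefficients use the standard closed form on the exponentialized
  pre-softmax score, `α = g² / (2g² + Σ_{ab}A_k(a,b) · g³)` with
  `0/0 → 0`, *normalized per channel to sum to 1*. The normalization makes
  the weighting a genuine weighted average: for spatially constant
  gradients `α ≡ 1/(HW)` and Grad-CAM++ reduces to Grad-CAM (tested), a
  property the unnormalized form does not have. The raw closed form itself
  is checked against numerical second/third derivatives.
* **Score-CAM** — gradient-free: each `A_k` is upsampled, min–max
  normalized (a constant channel maps to all zeros), multiplied
  element-wise into the input, and the masked images' pre-softmax class
  scores are softmaxed over channels into weights (a probability vector);
  map `ReLU(Σ_k w_k A_k)`.
* **Faster Score-CAM** — Score-CAM restricted to the `top_n = 10` channels
  with the largest spatial variance of `A_k` (descending; ties break
  toward the lower channel index; `K ≤ top_n` degenerates to Score-CAM
  exactly), softmax over the retained channels only.
* **Layer-CAM** — per-location weights `w_k(x,y) = ReLU(g_k(x,y))` where,
  in the default `"deviation"` mode, `g` is the gradient's deviation from its
  per-channel spatial mean; `"classic"` mode uses the raw gradient (the
  original formulation — both are provided because descriptions of the
  method differ, and on GAP-headed layers the deviation mode is
  identically zero since gradients are spatially constant). Channel
  combination `M = ReLU(Σ_k w_k A_k)` is rescaled per layer by
  `tanh(γ·M / max(M))` (γ = 2 by default, so each contributing layer's
  map peaks at tanh 2 ≈ 0.964; all-zero layers contribute zeros), layers
  are upsampled and fused element-wise by maximum (configurable to mean —
  maximum preserves fine shallow-layer detail). The default layer set is
  the last spatial layer of each resolution stage.

`binarize()` thresholds at `t_CAM` with `≥` (documented descriptions vary
between `>` and `≥`; `strict = TRUE` switches), optionally restricted to a
foreground mask. Nesting `t ≤ t′ ⇒ mask(t′) ⊆ mask(t)` holds by
construction and is property-tested across methods.

## Agreement statistics

`iou()` implements `|A∩B| / |A∪B|`. When *both* masks are empty the ratio
is 0/0; the package defines it as 1 — perfect agreement on "no damage" —
because at high thresholds empty masks are common and silently dropping
those pairs would bias the agreement distributions; `both_empty = NA`
excludes such pairs instead. `agreement_across_cams()` (model fixed,
φ_m) and `agreement_across_models()` (method fixed, φ_c) average IoU over
all unordered pairs, per slice and threshold; φ is computed on damaged
slices only, since no CAM is computed for the fresh class.

`correlate_with_liquid_loss()` reports Spearman's rank correlation between
a per-sample damage score — the mean CAM damage fraction over the sample's
slices, matching liquid loss's per-sample granularity — and the liquid-loss
percentage. A Shapiro–Wilk normality check of both inputs is attached for
logging, but the reported statistic is always the rank correlation (no
normality assumption). `compare_groups()` wraps the tie-corrected
Kruskal–Wallis H test; its type-I error calibration under an exchangeable
null is asserted in the acceptance suite (1000 simulations, 5% ± 2%).

When CAM-versus-truth overlap is judged, the chance reference is
`random_mask()`: a uniformly random foreground subset *area-matched to the
CAM mask* — the null of a predictor with the same positive rate.

## Pipeline and problem sizes

`run_pipeline()` executes the six stages (generate → split/preprocess →
train per architecture → CAMs for every damaged slice and (model, method)
pair → binarize over the grid → statistics) deterministically from one
seed, returning tidy per-slice tables plus a manifest of pair counts and
split sizes, and optionally writing CSV/JSON. The test suite exercises the
full study at reduced sizes chosen to keep a complete run on a single CPU
core in minutes: the end-to-end recovery test uses 20 samples × 8 slices
at 64×64 with the `"plain"` family across 10 seeds; the demonstration
script uses 6 samples per group across all three families and all five
methods, with augmentation off — at these severities the classes are
already separable, and augmentation is exercised separately in the unit
suite. These sizes are the package's own desk-scale choices; the agreement
statistics are size-agnostic.

## Known limitations

* The generator produces texture-realistic but physics-free images;
  absolute mIoU or φ values from synthetic runs do not transfer to real
  MRI.
* Backbones are desk-scale; while the contract (scores, activations,
  gradients) is what full backbones would expose, capacity-dependent CAM
  behaviour (e.g. very low-resolution deep layers) is not represented.
* Smoothed/integrated CAM variants (Smooth Grad-CAM++, Integrated
  Score-CAM, axiom-based variants), guided backpropagation and the
  downstream fully supervised segmentation stage of WSSS pipelines are out
  of scope.
* `shapiro.test` limits the normality log to 3–5000 observations; outside
  that range the gate is recorded as `NA` and the Spearman statistic is
  unaffected.
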