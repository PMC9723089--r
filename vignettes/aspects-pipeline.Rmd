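---
title: "Automated ASPECTS scoring on non-contrast CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ASPECTS scoring on non-contrast CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aspectsct)
```

## The problem

Early ischemic change (EIC) on non-contrast head CT is among the hardest
findings in emergency radiology: an acute middle-cerebral-artery (MCA)
infarct lowers tissue attenuation by only a few Hounsfield units, with no
sharp boundary, in images whose noise is of comparable magnitude. The
clinical summary of EIC burden is ASPECTS (Alberta Stroke Program Early CT
Score): ten MCA territories per hemisphere — caudate (C), insula (I),
internal capsule (IC), lentiform nucleus (L), and six cortical sectors
M1-M6 — each deducts one point from 10 when involved. Territories C, I,
IC, L and M1-M3 are assessed on the ganglionic axial level, M4-M6 on the
supraganglionic level.

`aspectsct` implements a complete automated pipeline: preprocessing,
symmetry-based input construction, dual-path convolutional segmentation,
affine atlas registration, territory scoring, and the statistical toolbox
used to evaluate such a system against and alongside human readers.

## Pipeline stages and their assumptions

### Detail enhancement

Each slice passes through a 3x3 median filter (edge handling by symmetric
reflection) and then a windowed gamma map: clip to the 0-80 HU brain
window, rescale to [0, 1], and apply `x^gamma` with `gamma = 0.6`. A
gamma below one expands contrast at the dark end of the window, where
hypodense ischemic tissue lives. The enhancement is strictly monotone, so
it never reorders intensities. The gamma map is a named, replaceable
stand-in for any preferred dark-detail enhancement; the interface fixes
only monotonicity and the [0, 1] range. Defaults: kernel 3 (smallest
effective), window 0-80 HU (standard brain window), gamma 0.6.

### Mirror assembly

Readers detect EIC by comparing hemispheres. The pipeline makes that
comparison explicit: estimate the midline, reflect the slice about it, and
stack (original, mirrored, difference) as three input channels. A
unilateral hypodensity of depth d appears in the difference channel as -d
at the lesion and +d at its mirror site, a signed, spatially localized
signature that survives even when the absolute HU drop is lost in noise.

The midline is found by exhaustive coarse-to-fine search over reflection
axes (angle within 15 degrees of vertical, offset within 20 px of centre),
scoring the negative mean squared difference between the image and its
reflection. For centred phantoms the configuration `midline = "center"`
skips the search. Reflection about non-pixel-aligned axes uses bilinear
interpolation; about the exact vertical centre axis it is a pixel
permutation, hence exact.

All three channels share one normalization; the image channels are then
centred by subtracting 0.5 (the mid-window intensity) so that every
channel is approximately zero-mean. That centring matters: with the raw
[0, 1] channels the network's early layers see a large common DC component
and gradient descent stalls on a uniform-probability plateau.

### The dual-path segmentation network

Two convolutional pathways view the same three-channel input:

* **Global path** — three stride-2 convolution stages (widths w, 2w, 2w)
  and a 1x1 prediction head on the stage-3 feature map, producing coarse
  foreground logits on a stride-8 grid. Its role is lesion-level
  localization: a low-resolution view with a wide receptive field.
* **Local path** — a full-resolution encoder with one down/up stage and a
  dense skip concatenation (the stage-1 features are concatenated with the
  bilinearly upsampled deeper features), ending in a 1x1 head at input
  resolution. Its role is boundary detail.

Both pathways' pre-sigmoid scores are bilinearly resized to the target
grid, **added element-wise**, and squashed with the logistic function.
Fusing on the logit scale (rather than adding probabilities) keeps the
fused map a probability for arbitrary inputs; identical pathway logits
`l` fuse to `sigmoid(2l)`.

Width and input size are configurable. The shipped `tiny` profile
(width 8, 64 px inputs) is the reference configuration for CPU-scale
phantom experiments and for all tests; a `full`-width preset (width 32,
512 px) exposes the same architecture at clinical resolution. All
convolution, resize and pooling kernels are implemented in C++ within the
package; gradients are hand-derived and verified against numeric
differentiation in the test suite.

### Loss and training

The loss is the unweighted sum of mean binary cross-entropy and a smoothed
Dice term, `1 - (2*sum(pt) + 1) / (sum(p) + sum(t) + 1)`. Cross-entropy
supervises every pixel; the Dice term concentrates gradient on the overlap
of small foregrounds. The smoothing constant 1 makes an empty prediction
against an empty truth cost zero. The relative weights default to 1:1 and
are configurable.

Training is SGD with momentum 0.9 over mini-batches of slices, a stepped
learning-rate decay, and early stopping: when the validation loss has not
improved for `patience` (default 5) consecutive epochs, training stops and
the best-validation weights are returned. The full-scale schedule starts
at `lr0 = 0.002` with decay factor 0.1 every 30 epochs for up to 100
epochs on 512 px inputs; the tiny profile uses `lr0 = 0.05`, factor 0.5
every 10 epochs, 40 epochs, batch size 8. Two schedule observations from
the phantom experiments informed these defaults: per-slice SGD at high
learning rates is unstable for this loss (mini-batches of 8 are used
instead), and decaying too fast freezes the network before the minority
deep-territory lesions are learned — cortical lesions are learned within a
few hundred updates, the smaller C/IC/L/I lesions need roughly 600.

### Atlas and registration

The package ships a programmatic two-level territory atlas standing in for
an MNI-derived supply-territory map: inside an elliptic brain, the
ganglionic hemisphere interior is partitioned into nested elliptic annuli
(C innermost, then IC, L, I) and three 60-degree cortical sectors (M1
anterior to M3 posterior); the supraganglionic level splits into sectors
M4-M6. Labels 1-10 are left C, I, IC, L, M1-M6; 11-20 the right
counterparts. The construction is exactly mirror-symmetric about the
vertical midline, and every region's area has a closed form, which the
tests check to within pixelation error (2%). A loader accepts any
user-supplied NIfTI label volume with the same label convention.

The atlas template is registered **to** the subject (never the reverse, so
patient data are not deformed) with a 5-parameter affine: rotation,
translation, anisotropic scale about the image centre. The objective is
the mean squared intensity difference. Optimization is initialized by
principal-axes moment matching — foreground centroids give translation,
second moments give scale and rotation (taken modulo 180 degrees) — and
refined by bounded quasi-Newton descent (L-BFGS-B) multi-started over
small angle offsets, with a final Nelder-Mead polish. The multi-start
guards against a genuine degeneracy: when anisotropic scaling makes the
head outline nearly circular, the moment angle is unidentifiable and the
intensity landscape grows shallow local minima a few degrees from the
truth. The template carries mirror-symmetric internal anatomy (denser
deep nuclei, hypodense frontal-horn ventricles) partly for realism and
partly because a featureless ellipse leaves rotation nearly unidentifiable
to any intensity metric. Labels follow the recovered affine with
nearest-neighbour interpolation, preserving the partition. On noiseless
phantoms the recovered transforms match truth to well under 0.1 px and
0.1 degree; the acceptance suite requires 1 px / 1 degree over 20 random
transforms.

### Region scoring and threshold calibration

For each territory k the overlap proportion is `rho_k = |lesion n
region_k| / |region_k|` — the denominator is the territory, since ASPECTS
asks whether the territory is involved, not how much of the lesion falls
in it. A region is called positive when `rho_k > tau`, and each
hemisphere's ASPECTS is 10 minus its positive count. Both hemispheres are
scored and reported separately. Regions absent from the scanned levels are
flagged and excluded from pooled analyses rather than silently scored 0.

The probability threshold `t` (lesion mask = probability > t) and overlap
threshold `tau` are calibrated jointly by grid search maximizing the
region-level Youden index (TPR - FPR) pooled over a validation cohort's
case-region outcomes — segmentation quality is judged by what it does to
region calls, not by voxel Dice. Ties break toward higher specificity,
then lower `t`. Defaults before calibration: `tau = 0.05` (any clear
involvement deducts the point), `t = 0.5`.

### Evaluation statistics

* **Region ROC/AUC** — thresholds enumerated on a fixed grid of 101 values
  in [0, 1]; at each, every case-region outcome (20 per case) is called
  via its overlap proportion; TPR/FPR are pooled over outcomes and AUC is
  the trapezoid over the swept path. On any finite instance this equals
  the Mann-Whitney probability of correct ranking, which the tests assert
  to 1e-12.
* **AUC confidence interval** — a seeded case-level bootstrap (2000
  replicates, percentile interval). Resampling whole cases preserves the
  within-case correlation of the 20 outcomes. This is the package's
  documented stand-in for parametric AUC interval methods; the method name
  is recorded in output metadata.
* **Segmentation metrics** — Dice, precision, recall with documented
  empty-mask conventions (both empty: all 1; an empty denominator under
  disagreement: 0).
* **Reader statistics** — ICC(A,1) (two-way, single rater, absolute
  agreement) computed from the package's own mean-squares arithmetic and
  cross-checked against `stats::aov` in the tests; McNemar on discordant
  pairs (chi-squared without continuity correction for b + c >= 25, exact
  two-sided binomial otherwise); paired t for reading times; jackknife
  (leave-one-case-out pseudovalue) 95% intervals for average reader
  sensitivity and specificity. All tests are two-sided at alpha 0.05.

## The synthetic phantom: what it does and does not emulate

Every stage is exercised on generated data. A phantom is a two-slice
(ganglionic + supraganglionic) 2-D head: skull ring at 700 HU, brain
tissue at 35 HU with 2 HU Gaussian noise, deep nuclei +5 HU, CSF
ventricles at 5 HU, air at -1000 HU. ASPECTS is defined on two axial
levels, so two 2-D slices capture the scoring geometry at a fraction of
3-D cost. Subjects are generated from the template under random affines
(rotation within 10 degrees, translation within 10 px, scale 0.9-1.1) plus
noise, with the true transform stored for registration tests.

Lesions emulate the one property of EIC that drives the whole design:
subtle hypodensity with fuzzy boundaries. A lesion lowers HU by a default
8 HU (about 4 noise SDs, at the subtle end of visible EIC) inside a blob
grown by thresholding a smoothed random field at the per-region quantile
that covers `lesion_fill` (default 0.8) of each target territory — fuzzy,
connected, and with exactly known region truth. Cohorts draw each of the
20 region outcomes as independent Bernoulli(prevalence = 0.1), roughly
matching an external-validation-like mix of mostly high ASPECTS.

What the phantom does **not** model: CT physics (beam hardening, partial
volume, streaks), anatomical variation beyond affine geometry, non-MCA
territory, old infarcts or leukoencephalopathy, and real lesion texture.
Passing phantom tests therefore demonstrates that the machinery —
symmetry encoding, learning, registration, scoring, statistics — is wired
correctly and is sensitive at realistic contrast-to-noise, not that the
trained weights transfer to patients.

## Problem sizes and numerical choices

Reference experiment sizes, chosen to keep a complete run at desk scale:
phantom grid 128 px (atlas geometry tests use 512), model inputs 64 px,
width 8, training cohort 100 cases (200 slices, 40 validation slices),
held-out cohort 30 cases, 40 epochs. Under these conditions the held-out
region-call accuracy exceeds 0.9 and the pooled region AUC exceeds 0.85,
with registration in the loop.

Numerical conventions worth knowing:

* Coordinates are 1-based pixel centres (x = column, y = row); resampling
  uses the half-pixel convention with clamp-to-edge; masks and labels
  always travel by nearest-neighbour.
* Probabilities are clamped to [1e-7, 1 - 1e-7] inside the cross-entropy.
* The lesion-free difference-channel bound (max below 3 noise SD) holds
  for the denoised channel the pipeline actually feeds the network; raw
  Gaussian noise would exceed any fixed multiple of sigma on a large
  enough slice.
* Thresholding of the fused probability map happens after mapping back to
  the source grid.
* `set.seed` governs every stochastic component: cohort generation,
  weight initialization, shuffling, bootstrap.

## Known limitations

2-D slice-level processing (no volumetric context); affine-only
registration (no deformable refinement, no mutual-information metric for
multi-modal use); the dark-detail enhancement is a generic gamma map; the
AUC interval is a bootstrap rather than a closed-form method; the tiny
profile's capacity is deliberately small and its decision quality on real
NCCT is untested and untestable here.
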