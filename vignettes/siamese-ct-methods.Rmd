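---
title: "Multi-task response assessment on longitudinal CT: models and methods"
author: "SiameseCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task response assessment on longitudinal CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-grade serous ovarian carcinoma typically presents as multi-site
metastatic disease: pelvic/ovarian masses plus omental deposits spread
across the abdomen. Response to neoadjuvant chemotherapy is read from
paired contrast-enhanced CT scans (baseline before treatment, follow-up
after), conventionally by RECIST 1.1 diameter measurements on a few
target lesions. `SiameseCT` implements a multi-task alternative: a
single network that *segments* the two main disease sites in both
scans and simultaneously *classifies* the pair as responder versus
non-responder from voxel-wise changes in its own feature maps.

# The model

The backbone is a 3D U-Net. Each encoder level applies a
3×3×3 convolution with stride 2 that doubles the channel count
(capped), followed by a pre-activation residual context block: instance
normalisation, leaky ReLU (slope 0.01), 3×3×3 convolution, dropout,
instance normalisation, leaky ReLU, 3×3×3 convolution, and a residual
addition. Each decoder level starts with a localisation module — a
3×3×3 convolution whose output is carried to the next finer resolution
by trilinear upsampling — concatenates the encoder skip at that
resolution (at full resolution the skip is the input volume itself,
since the first encoder convolution already has stride 2), and merges
with another 3×3×3 convolution. Every decoder level carries a
deep-supervision segmentation head (1×1×1 convolution to three class
logits: background, omental, pelvic/ovarian).

Both time points run through *the same parameter set* (a Siamese
arrangement; sharing is structural, not copied). Three feature taps per
stream feed the response head: the context-block output of the middle
encoder level, the bottleneck, and the penultimate decoder feature map
before the final classifier. The head subtracts the taps voxel-wise
(pre minus post), passes each difference map through a bias-free
depth-wise 3×3×3 convolution and a bias-free point-wise projection to
32 channels, global-averages each channel, concatenates the three
32-vectors and maps them with a single linear layer to one response
logit. Because the head is bias-free up to the final linear layer,
identical inputs yield exactly the linear layer's bias — a contract the
tests assert.

Design points that the architecture description leaves open, and the
choices made here:

* *Tap placement.* "Middle of the contracting path" is read as the
  context-block output of level ⌈L/2⌉; the "combination module"
  tap is the last decoder feature map before the 1×1×1 classifier.
* *Depth-wise head with 32 outputs.* Tap channel counts generally
  differ from 32, so each stream owns a depth-wise (per-channel) 3×3×3
  filter followed by a point-wise projection to exactly 32 channels.
* *Localisation module order.* The 3×3×3 convolution is applied at the
  coarser grid and its output is upsampled trilinearly. Convolving
  before upsampling is mathematically the natural reading of a module
  that "upsamples the feature maps" and costs a quarter of the
  full-resolution alternative.
* *Single-logit head.* The binary response uses one sigmoid logit with
  binary cross-entropy, the two-class special case of the softmax
  cross-entropy form.

Defaults are `nLevels = 5`, `baseChannels = 32`, `channelCap = 320`,
`dropoutP = 0.3`; the desk-scale configuration used throughout the
tests is `nLevels = 3`, `baseChannels = 8`.

# Losses and training schedule

Segmentation uses the soft multi-class Dice loss
$$L_{DSC} = 1 - \frac{1}{C}\sum_{c=1}^{C}
  \frac{2\sum_i \hat y_{i,c} y_{i,c} + \epsilon}
       {\sum_i(\hat y_{i,c} + y_{i,c}) + \epsilon}$$
plus weighted cross-entropy, evaluated at every decoder resolution with
level weights halving per coarser level (normalised to sum to one); the
ground truth is downsampled by nearest neighbour. The smoothing
constant is $\epsilon = 10^{-5}$; ground truth enters the Dice loss
one-hot. The cross-entropy normalises by the sum of applied weights
(the standard weighted-mean form), which reduces to the plain mean for
unit weights and is invariant to rescaling all weights. A pair's
segmentation loss is the mean over its two scans. The total loss is
$\lambda_1 L_{class} + \lambda_2 L_{seg}$ with $\lambda_1 = 1$,
$\lambda_2 = 0.2$, so response classification dominates.

Training uses Adam (the optimiser is not prescribed by the
architecture; Adam with default moments is the conventional choice),
batch size 2, linear warm-up over the first 4% of steps to a peak
learning rate of $5\times10^{-5}$, then cosine decay to zero. Early
stopping monitors validation response AUC every `valInterval` steps
with a patience counter; the best-AUC parameter snapshot is retained,
and among AUC ties the most recent snapshot is kept because the
segmentation branch keeps improving after the response branch
saturates. Validation splits are drawn by case, never by scan.

All computation is CPU-native: 3D convolutions are evaluated as
tiled im2row + single-precision BLAS matrix products with hand-written
backward passes, which keeps the patch matrices cache-resident. The
backward data pass is computed as a correlation with the flipped
kernel so one patch matrix serves both the data and the weight
gradients.

# Preprocessing

Scans are attenuation-clipped to $[-150, 250]$ HU (inclusive), mapped
linearly to $[0,1]$, and resampled to $5 \times 0.8 \times 0.8$ mm
voxels (trilinear for images, nearest-neighbour for masks, about the
grid centre). The follow-up scan is rigidly registered onto the
baseline grid — baseline is the fixed image, so the response head's
"pre minus post" differences live on the baseline grid. The metric is
mutual information (32-bin joint histogram); optimisation is
multi-resolution (in-plane factors 4/2/1; the slice axis, already
coarse at 5 mm, is downsampled less) with Nelder–Mead. Robustness and
precision come from three measures chosen after studying the metric's
landscape on phantoms: (1) the optimisation metric is computed on
volumes smoothed with an isotropic-in-mm Gaussian (σ = 1.2 mm), which
removes spurious noise-induced local optima and, being isotropic,
commutes with rotations so it does not bias the optimum; (2) the
coarsest level runs a translation-only fit and a rotation grid search,
and every level alternates rotation-only and translation-only simplex
fits before the 6-dof polish — 3-dof problems are far less prone to
the flat, coupled valleys that stall a cold 6-dof simplex; (3) a final
coordinate-wise Brent polish on the raw (unsmoothed) metric recovers
sub-voxel precision. Registration accuracy on phantoms is about a
quarter voxel in translation; in-plane rotation, which is only weakly
identified by a smooth body outline, is recovered to a few tenths of a
degree.

# Paired augmentation

Per training pair one affine matrix is sampled — per-axis flips
(p = 0.5), isotropic scale 0.85–1.15, shear ≤ 0.1, per-axis rotations
≤ 15°, each with application probability 0.15 — and applied identically
to both volumes and both masks (trilinear / nearest-neighbour, about
the volume centre, out-of-field filled with 0), so the pair stays
co-aligned. Grey-value transforms are drawn independently per time
point in the fixed order shift (±0.1) → scale (0.9–1.1) → Gaussian
noise (σ ≤ 0.05) → Gaussian smoothing (σ 0.5–1 voxels) → contrast
(0.75–1.25 about the mean), and the result is re-clamped to $[0,1]$.
The ranges are conventional medical-imaging magnitudes; none is stated
by the architecture description, and all are exposed in
`augmentConfig()`.

# The synthetic phantom

No clinical data ship with the package; every end-to-end claim is
exercised on a synthetic longitudinal phantom designed to contain
exactly the structure the model needs — no more:

* an eccentric soft-tissue ellipsoid body (about 40 HU) in air
  (−1000 HU), tapering towards both ends of the scan range. The
  eccentric, tapered shape is deliberate: it makes all six rigid
  degrees of freedom anatomically identifiable, which a cylindrical
  phantom would not;
* two disjoint disease regions: pelvic/ovarian lesions (label 2) in
  the caudal slices placed centrally/dorsally, omental deposits
  (label 1) in the ventral half of the cranial slices — the
  ventral-versus-central placement is the positional cue that lets a
  segmentation network separate two otherwise identical lesion
  classes, standing in for the rich anatomical context of real CT;
* ellipsoidal lesions of 3.5–7 mm base radius at 90–140 HU, with
  independent Gaussian HU noise (σ = 15, clamped at 4σ) per time
  point.

Follow-up lesions are the baseline lesions rescaled about their
centres by independent per-lesion factors constrained to a case-level
RECIST 1.1 category (partial responders target a 35–55% diameter-sum
reduction, complete responders lose all lesions, stable disease stays
within ±15%, progression grows ≥ 28%), modelling per-lesion response
heterogeneity. The emitted label is *always recomputed from the masks*
by the package's RECIST labeller — each connected lesion component is
measured by its longest in-plane diameter (maximum pairwise voxel
distance within a slice, with a one-voxel floor so residual disease is
never measured as zero), summed over all lesions, and classified by
the 30%/20% thresholds; the labeller measures every lesion rather
than a radiologist-style target subset.

What the phantom does *not* emulate: organ anatomy, contrast phases,
breathing or deformable motion between time points, new-lesion
appearance, and CT texture. Passing the desk-scale experiment
therefore shows that the implementation can recover a size-change
signal end-to-end; it says nothing about clinical performance on real
cohorts.

# The desk-scale experiment

The acceptance experiment trains the full multi-task model on 64
synthetic pairs (20 held out) on a 32×64×64 grid with the 3-level,
8-channel configuration for up to 800 steps at a peak learning rate of
$2\times10^{-3}$ (a short-run rate; the $5\times10^{-5}$ default is
tuned for runs three orders of magnitude longer), dropout disabled (at
this scale validation phantoms come from the same generator as the
training ones, so there is no distribution shift for dropout to guard
against), validation every 50 steps with patience 12, flips-only
augmentation,
and segmentation class weights (1, 8, 8). Full-strength augmentation
is regularisation for runs of ~10^5 iterations; at this budget the
grey/affine transforms (in particular 0.5–1 voxel smoothing on 5 mm
slices and 15° rotations) smear lesions spanning one or two slices
into effective label noise and measurably slow segmentation learning,
so the experiment keeps only the flips. The foreground upweighting reflects that lesions
occupy well under 1% of phantom voxels; with unit weights the
background term dominates the cross-entropy and the network needs far
longer to leave the all-background solution. For the same reason the
deep-supervision heads are initialised at the background prior (bias
−4 on the two lesion-class logits) rather than uniform, the standard
initialisation under extreme class imbalance. Problem sizes were chosen so the whole
experiment — cohort generation, training, evaluation — runs in minutes
on one CPU core. Expected behaviour: an untrained network scores an
AUC statistically indistinguishable from 0.5, while the model at the
end of the schedule reaches validation AUC ≥ 0.85 and mean foreground
Dice ≥ 0.6. Because the response branch saturates long before the
segmentation branch, the experiment evaluates the end-of-schedule
network; the best-AUC checkpoint is still retained for deployment.
Only left-right flips are enabled as spatial augmentation anywhere in
the package's defaults: mirroring the cranio-caudal or ventral-dorsal
axis is not an anatomy-preserving symmetry once lesion classes are
defined by anatomical site, and was observed to erase exactly the
positional cue that separates the two classes.

# Evaluation stack

Response scores are evaluated by ROC analysis: the AUC in its
Mann–Whitney form (ties count one half), a case-level percentile
bootstrap 95% interval (resamples with a single class are redrawn; the
interval method is a choice — an analytic DeLong interval would be the
main alternative), and an operating point maximising Youden's J over
all observed score thresholds with ties broken toward higher
sensitivity and then the lower threshold. Sensitivity, specificity,
PPV, NPV and support-weighted precision/recall/F1 are reported at that
point. Segmentations are scored per class by the Dice similarity
coefficient of the full-resolution argmax; a class empty in both
prediction and truth scores 1 (this matters for complete responders).

Grad-CAM relevance maps use the global-average gradient of the chosen
target as channel weights on the corresponding feature map — for the
response target, the difference features of a chosen tap (bottleneck
by default); for a segmentation class, the final decoder features —
rectify the weighted sum, upsample trilinearly to the input grid and
scale to $[0,1]$. A target with no gradient path onto the chosen
features yields an all-zero map with a warning.

# Numerical and degenerate-input conventions

* Clipping boundaries −150 and 250 HU are inclusive; normalisation is
  guarded against double application.
* Resampling and affine transforms act about the grid centre;
  0-based voxel indices map to physical mm as
  $(i - (n-1)/2)\,\Delta$.
* Nearest-neighbour label resampling can only ever shrink the label
  set.
* An empty baseline mask has no measurable disease and is an error;
  an empty follow-up mask is a complete response.
* AUC and Youden operating points require both classes; a single-class
  validation split is rejected when training starts.
* Non-finite training loss aborts with a diagnostic rather than
  continuing silently.

# Known limitations

The phantom's homogeneous body makes in-plane rotation the
least-identified registration parameter; accuracy there is a few
tenths of a degree rather than the hundredths achievable with textured
anatomy. Whole-volume training is used throughout (no patch sampling),
so very large real volumes would need the documented centre crop/pad
path. The desk-scale network is far smaller than a clinical-scale
model, and no claim about the reported clinical performance of the
full-scale system can be derived from the synthetic experiments.
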