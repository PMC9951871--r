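---
title: "Inpainting-based self-supervised pretraining for segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inpainting-based self-supervised pretraining for segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inpaintssl)
```

## The problem

Segmentation networks for medical images are label-hungry, and expert
annotations are the scarcest resource in the pipeline. Self-supervised
pretraining sidesteps this by first training the network on a *pretext
task* that needs no labels: the image is deliberately corrupted and the
network must reconstruct the original ("inpainting"). The hope is that a
network that can restore plausible anatomy has learned image-level
features that transfer to segmentation, so that fine-tuning needs far
fewer labeled scans.

`inpaintssl` implements this paradigm end to end for 2D MRI and CT
slices: two corruption-based pretext tasks, the corruption samplers and
mask banks, a U-Net whose weights are partitioned for selective
transfer, the pretraining and fine-tuning loops, clinically relevant
evaluation metrics, and the statistics used to compare pretraining
strategies and to characterize data scaling. A phantom generator makes
the whole pipeline testable on one CPU with analytically known ground
truth.

## Pretext tasks and corruption geometry

Both tasks corrupt square K × K patches until at least one quarter of
the image area is affected, and both are specified purely by geometry
(a "mask"), so masks can be precomputed and reused across images:

* **Context prediction** sets the patch pixels to zero. Images are
  corrupted *after* standardization, so zero is the unit's mean
  intensity.
* **Context restoration** swaps the contents of pairs of
  non-overlapping patches. This preserves the image's pixel-value
  multiset exactly — the network cannot cheat by learning a global
  intensity prior, it must restore the *arrangement*.

Patches are selected iteratively; the patch (or pair) that first
reaches the quarter-area target is kept whole. The corrupted fraction
therefore always lies in `[1/4, 1/4 + s/(HW))`, where `s` is the pixel
count added per iteration (K² for a patch, 2K² for a pair). Coverage is
counted as the union of corrupted pixels, so overlapping random patches
are not double counted; for swapped pairs, both patches of the pair
count toward the corrupted area (the union convention — the defensible
alternative of counting only one patch per pair would merely rescale K
and was not adopted).

Two samplers place the patches:

* **random** — anchors uniform over all in-bounds positions; patches
  may overlap.
* **poisson** (Poisson-disc) — dart throwing with a rejection rule:
  a candidate is accepted only if its patch center is at least K·√2
  (Euclidean) from every accepted center. K·√2 is the *smallest*
  center-distance bound that guarantees two axis-aligned K × K patches
  cannot overlap: if both coordinate offsets were below K, the distance
  would be below K·√2. We use plain dart throwing rather than a
  maximal-sampling construction (e.g. Bridson's algorithm) because only
  the distance constraint matters and the densities involved are far
  from the jamming limit for K ≥ 16; for K = 8 at 512 × 512 the target
  (1024 points) sits at roughly three quarters of the saturation
  density, which dart throwing still reaches reliably. The sampler
  restarts from scratch if it stalls and errors after bounded retries —
  relevant mainly near the feasibility boundary `K = min(H, W)/3`,
  where an unluckily centered first dart can block the remaining
  placements.

Anchors are 0-based top-left corners with half-open extents
`[r, r+K) × [c, c+K)`. Masks rotate by quarter turns with exact integer
coordinate algebra (a 180° turn maps `(r, c)` to `(H−r−K, W−c−K)`), so
a **mask bank** of 100 precomputed masks provides 400 effective masks
under the four rotations; a fresh rotated mask is drawn uniformly for
every image at every training step. For multi-channel CT input the same
spatial mask is applied to every channel, so corruption locations can
never act as a channel-discriminating shortcut.

## Preprocessing

CT slices are expanded to three channels by Hounsfield-unit windowing —
soft tissue (W/L = 400/50), bone (1800/40) and a custom setting
(500/50); a window of width W at level L clips to `[L−W/2, L+W/2]` and
leaves in-window values untouched (values stay in HU; all rescaling is
left to normalization). Every input is then standardized to zero mean
and unit variance — MRI per volume (a standalone 2D image is its own
unit), CT per windowed channel. The means and standard deviations are
returned so reconstructions can be mapped back to original units.
Clinical HU statistics are always computed on the raw, un-windowed,
un-normalized image so that they remain physically meaningful.

## The network

A 2D U-Net with two 3 × 3 convolution blocks per resolution level
(weight-standardized convolution → Group Normalization → ReLU), 2 × 2
max-pool downsampling, 2 × 2 stride-2 transposed-convolution upsampling
and concatenation skip connections. Channel width doubles per level.
Weights are He-initialized (fan-in, normal) under a seed, so builds are
reproducible. Group Normalization (default 8 groups, ε = 1e−5) rather
than batch normalization keeps training independent of the small batch
sizes this problem uses. Weight standardization re-parameterizes each
kernel to zero mean and unit variance per output filter at use time
(ε = 1e−7 on the variance; this small floor keeps even low-variance
He-initialized kernels within tight tolerance of unit variance).
Gradients flow through the standardization map. The final 1 × 1
convolution — the *post-processing layer* — is the only place the two
heads differ (output channels = input channels for inpainting, 4
classes for segmentation) and is the one convolution without weight
standardization, since no normalization follows it and the output scale
must be free.

The parameters are partitioned into three disjoint, total scopes used
by transfer learning: **encoder** (contracting path including the
bottleneck), **decoder** (transposed convolutions and everything after
a skip concatenation — the first convolution after each concatenation
belongs to the decoder) and **post_processing**. Transfer copies either
the encoder only or encoder and decoder; the post-processing layer is
never transferred (its shape differs between heads anyway). Freezing is
per scope and is exact: a frozen tensor is bit-identical across a
training phase.

The exact layer counts and widths are configurable because they are not
part of the method's contract; only the scope partition, the head
behavior and the normalization scheme are normative. Defaults are
`depth = 4`, `base_filters = 16`; the phantom-scale experiment plans use
`depth = 3`, `base_filters = 8` (see *Problem sizes* below).

## Training protocol

Optimization is ADAM with β₁ = 0.99, β₂ = 0.995 and batch size 9 by
default, with early stopping on the validation objective (default
patience 10 epochs, cap 200; these two values are the package's own
defaults — the protocol this implements specifies early stopping
without printing its parameters). Training always returns the
best-validation weights, not the last.

*Pretraining* minimizes the pixelwise mean squared error between the
reconstruction and the uncorrupted image, computed over the full image
(not only the corrupted region — restricting to masked pixels is a
variant, not the default, and the full-image objective also penalizes a
network that corrupts intact regions). Mean squared error is a monotone
transform of the Euclidean (L2) norm, so the minimizers coincide while
magnitudes stay comparable across image sizes; the *evaluation* metric
is the true L2 norm — per channel, averaged over channels for
multi-channel CT — so reported reconstruction errors are on the
conventional scale.

*Fine-tuning* minimizes the soft Dice loss, aggregated over mini-batches
per class: the per-class sums `Σp`, `Σg`, `Σpg` pool over every pixel of
the whole batch before forming `D_c = (2Σpg + ε)/(Σp + Σg + ε)`, and the
loss is `1 − mean(D_c)` over the four foreground classes (ε = 1e−7;
background is "none of the four classes" and contributes no Dice term).
Two schedules are provided: `immediate` (all weights trainable from the
start) and `freeze_then_unfreeze` (transferred scopes frozen until early
stop, then everything unfrozen with a restarted optimizer; the second
phase's learning rate defaults to the first's and may be set lower,
e.g. 1e−3 then 1e−4). The default strategy object encodes the
combination found most beneficial across modalities: context
restoration, 32 × 32 patches, Poisson-disc sampling, encoder-only
transfer, immediate fine-tuning at 1e−3.

Label-limited regimes use nested subsets (5% ⊆ 10% ⊆ 25% ⊆ 50% ⊆ 100%)
drawn from a single seeded shuffle. Sizes follow
`max(1, round-half-up(fraction × n))`; published cohort tables
occasionally round differently in different directions (e.g. 4.3 → 5
but 35.45 → 35 in the cohorts this mirrors), so exact printed sizes can
be imposed per fraction via the `sizes` argument rather than by
guessing an inconsistent global rule.

## Evaluation and statistics

Segmentations are discretized by argmax over the four class
probabilities, with a pixel assigned to background when no class
exceeds 0.5 (the threshold is exposed; 0.5 is the natural choice for a
4-way softmax where "winning without majority" indicates no foreground
support). Metrics: per-class Dice (defined as 1 when both masks are
empty), tissue volume (pixels × spacing² × thickness), mean T2 over the
predicted mask, cross-sectional area (pixels × spacing²), and mean HU
on the raw image. Percent errors compare prediction-derived to
ground-truth-derived values as magnitudes, `100·|pred − gt|/|gt|`
(signed errors are logged for diagnostics); a zero ground truth yields
`NA`, never a silent zero. The headline Dice aggregates per class per
volume → mean over volumes → mean over classes. Per-image comparisons
average each arm's percent error over classes and label regimes, one
row per test image, with optional class exclusion (tiny-area classes
such as intramuscular fat produce percent errors in the thousands and
would swamp the average).

Strategy ranking pools each strategy's class-averaged per-image Dice
scores across the 50/25/10/5% regimes (pooling is the default; a
per-regime option exists because the pooling granularity is a judgment
call) and tests them against the paired supervised scores with a
one-sided Wilcoxon signed-rank test. For n ≤ 12 the null is enumerated
exhaustively over all 2ⁿ sign assignments — exact even under midranked
ties; larger n uses the normal approximation with tie-corrected
variance and no continuity correction. Zero differences are dropped
(standard signed-rank convention). Strategies are sorted by ascending
p-value per dataset and the strategy appearing in every dataset's top
three is selected; an empty intersection is reported explicitly as "no
consensus" rather than silently picking a winner. No multiplicity
adjustment is applied across the strategy grid — the ranking consumes
raw p-values as ordering scores, not as calibrated error rates.

Data scaling is summarized by fitting `y = a·xᵏ + c` to mean test Dice
versus pretraining-data amount (x in percent of the standard training
set; the supervised baseline enters as x = 0, which is why k is
constrained positive — `0ᵏ = 0` maps the baseline to `c`). Three-
parameter power laws on a handful of points are initialization-
sensitive, so the fit profiles out the linear parameters (for fixed k
the model is linear in a and c), multi-starts the 1-D search over k at
{0.1, 0.3, 0.5, 0.7, 1.0}, and polishes with Levenberg–Marquardt,
keeping the best residual sum of squares. Goodness of fit is the
residual standard error `S = sqrt(Σ(yᵢ − ŷᵢ)²/(n − 2))`, with the n−2
denominator as conventionally printed for this quantity. At least four
distinct x values are required; the phantom-scale sweep therefore
defaults to four pretraining levels {0, 25, 50, 100}%.

## The phantom generator

Phantoms exist so every stage is testable without external data, with
ground truth that is exact by construction. Each phantom is four
axis-aligned elliptical structures (one rendered as an annulus), one
per image quadrant with jittered centers and radii bounded so the
structures stay disjoint and fully inside the image; each class is
guaranteed at least 0.5% of the pixels. Intensities are constant per
class (HU values within [−1024, 3071] for CT) plus additive Gaussian
noise (default σ = 5, roughly 5% of the smallest class contrast — enough
to make normalization well-defined and denoising non-trivial without
burying structure); MRI phantoms carry a piecewise-constant T2 map, so
mean-T2 recovery is analytically checkable. Everything is deterministic
in (seed, index), and datasets written to disk (NIfTI images, label
maps, T2 maps, CSV manifest) round-trip exactly for integer grids and
to 1e−6 for floats.

What phantoms deliberately do **not** emulate: anatomical texture and
correlated noise, partial-volume boundaries, intensity inhomogeneity,
inter-subject variability, or any MR/CT physics. Consequently, passing
tests establish that the machinery is correct — corruption geometry,
losses, transfer, metrics, statistics — not that SSL pretraining will
improve segmentation on real scans, and phantom-scale Dice differences
between SSL and supervised arms are reported, never asserted.

## Problem sizes and numerical choices

Phantom-scale defaults are sized for a single CPU: 96 × 96 images,
depth-3 U-Net with 8 base filters, a dozen unlabeled and eight labeled
phantoms, short early-stopped schedules. The end-to-end smoke runs at
128 × 128 because 32 × 32 Poisson-disc corruption requires
min(H, W) ≥ 3K. The full-scale geometry (512 × 512, depth 4-5) is
exercised where it is cheap — corruption, mask banks and their
invariants all run at 512 × 512 — while training-loop checks use the
small sizes; training at the full 512 × 512 scale is a GPU-class
workload out of scope for this implementation's test envelope.

Numerical details worth knowing: Group Normalization and weight
standardization use population variance with additive ε (1e−5 and 1e−7
respectively); a constant kernel standardizes to zero rather than
dividing by zero. Max-pool ties break toward the earliest element in
column-major order. The Dice loss ε makes empty-class Dice equal 1
(both for the loss and for the hard [0,1] `dice_score`, where
empty-vs-empty is 1 by convention). ADAM uses bias correction and
ε = 1e−8. All randomness flows through R's RNG — including the
compiled Poisson-disc sampler, which consumes R's uniform stream — so a
single `set.seed()` makes any pipeline run bit-reproducible.

## Limitations

The implementation is 2D and single-backbone (U-Net); 3D convolutions,
attention variants and other optimizers are out of scope. The
freeze-then-unfreeze schedule restarts the optimizer between phases;
carrying ADAM moments across the unfreeze boundary is a plausible
variant not implemented. The corruption machinery supports non-square
images except for 90°/270° mask rotations, which require square
geometry. Fractional-area targets other than ¼ are available as a knob
(`target_fraction`) but are untested territory scientifically.
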