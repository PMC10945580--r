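---
title: "Methods: segmenting and quantifying synaptic puncta in 3D stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and quantifying synaptic puncta in 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

punctaseg quantifies punctate fluorescent signals — synaptic reporters such
as CLA-1, RAB-3, GRASP, or tagged innexins in *C. elegans* — from 3D
confocal stacks. The pipeline has four stages: neurite masking, synapse
segmentation, puncta quantification, and evaluation. This vignette records
the models behind each stage, the tunable parameters and their defaults,
the design decisions taken where the design was genuinely open, and what
the synthetic-data tests do and do not demonstrate.

## Neurite masking: a 2.5D U-Net

Restricting synapse calling to the neuron of interest is what makes the
pipeline robust in tissue with autofluorescence (intestine, coelomocytes)
and in synapse-dense neuropil. The mask is predicted by a U-Net that reads
a chunk of `depth = 7` consecutive z-slices of the cytoplasmic channel and
predicts the binary neurite probability of the center slice. Treating the
seven slices as input channels of a 2D encoder–decoder is a standard 2.5D
formulation: each prediction sees 3D context at a fraction of the memory
and compute of full 3D convolution, and the skip connections operate on 2D
feature maps throughout. We chose this over mixed 3D-encoder/2D-decoder
variants because the two deliver comparable masks on tubular structures
while the all-2D network has a much simpler and faster backward pass; the
network here is implemented natively (forward, backward, Adam) with no
external deep-learning dependency.

* Architecture: `levels = 4` resolutions, `base = 16` feature maps doubling
  per level (16→128), two 3×3 convolutions + ReLU per block, 2×2 max
  pooling, nearest-neighbor upsampling, skip concatenation, 1×1 output
  convolution with a sigmoid.
* Loss: `L = L_IoU + L_CE`. The soft IoU term,
  `1 − (Σpt + ε)/(Σp + Σt − Σpt + ε)` with `ε = 1e-6`, directly targets the
  overlap metric and counteracts the extreme foreground/background
  imbalance of thin neurites; the cross-entropy term stabilizes early
  training. The loss is 0 exactly at a perfect binary prediction.
* Optimization: Adam at `lr = 0.001`, at most 200 epochs, random
  flip/rotation augmentation per epoch, early stopping on validation loss
  with patience 20 (the best-validation weights are restored). Training
  stacks are sampled into 200 random patches each, and blank patches are
  discarded by a mean-intensity threshold (`blank_threshold`, default 0 =
  keep everything; raise it on stacks dominated by empty background).
* Inference: chunks are reflect-padded in z at the stack boundaries, the
  frame is tiled laterally (tiles overlap when the frame is not a tile
  multiple), and tiles are stitched by ownership ranges placed at overlap
  midpoints, so every voxel is predicted exactly once. The probability map
  is thresholded at 0.5.
* Soma removal (`remove_somata`, off by default): regions whose in-plane
  thickness exceeds `soma_diameter` are found by iterated in-plane erosion
  and removed after re-dilation, so soma-localized puncta can be excluded
  downstream. The thickness criterion is this package's own device: it
  needs no seed points and cannot remove a thin neurite, but it will spare
  a soma thinner than the configured diameter.

The package's tests train a scaled-down configuration — 2 levels, 8 base
feature maps, 64×64 tiles, 8 patches per stack, at most 25 epochs on 10
synthetic training stacks — which reaches held-out tube IoU above 0.95 in
about a minute on one CPU core. These sizes are the package's reference
problem sizes for desk-scale verification; the default 4×16×256 model is
what one would train on real microscopy data.

## Synapse segmentation: a two-layer pixel classifier

Puncta are segmented by a pixel classifier over local image features, in
two layers.

**Features.** Nine filters per channel: raw intensity, in-plane Sobel
gradient magnitude, difference of Gaussians at scale pairs (1,2) and (2,4)
voxels, Laplacian of Gaussian at scales 1 and 2, local mean and standard
deviation in a 3×3×3 window, and grayscale erosion with a 3×3×3 element.
Sobel/DoG/LoG are 2D per slice (confocal stacks are strongly anisotropic
in z), mean/sd/erosion are 3D. The two Sobel derivatives enter as a single
gradient magnitude, keeping the vector at 9 per channel; the synapse
channel is always present, the cytoplasmic channel contributes 9 more when
available. Scales {1, 2, 4} bracket the 1–3 voxel small-punctum regime and
are configurable per preset (`feature_bank()`). Features are standardized
by a scaler fit on the training pixels only.

**Layer 1, step 1.** Training pixels are all positive (labeled) pixels
plus negatives sampled within a 2-voxel dilation band around them, at 3
negatives per positive. Both knobs are configurable (`neg_band`,
`neg_ratio`); "near the positives" is deliberately tight so that the first
fit concentrates on the hardest boundary pixels.

**Layer 1, step 2 (hard-negative mining).** A classifier trained only near
puncta over-calls elsewhere. The trained step-1 model therefore predicts
over patches ten times the training patch side, and the negatives it marks
positive — its actual false positives — are added before refitting. A
`harvest = "false_negative"` flag implements the alternative reading
(re-adding missed positives); since every positive pixel is already in the
training set, that variant leaves the set unchanged, which is why the
false-positive reading is the default.

**Patch plan.** Training work is restricted to slice tiles containing
positive pixels; the tile side is `round(2·sqrt(mean 2D connected-label
area))`, floored at 3. Every positive pixel lies in a kept tile by
construction.

**Layer 2.** Each pixel's feature vector is extended with the layer-1
probabilities of its six face neighbors (±1 in z, y, x; neighbors outside
the volume take the center pixel's probability), and a second classifier
of the same family is trained on the same pixels. Spatial context makes
isolated bright voxels less credible and punctum-adjacent voxels more so.

**Classifiers.** Random forest by default (`ranger`), with SVM (`e1071`)
and a single-hidden-layer MLP (`nnet`) as options. Hyperparameters come
from a grid search with stratified 5-fold cross-validation selecting on
positive-class F1; the default RF grid is trees {100, 300} × depth
{unlimited, 16}, and the SVM/MLP grids are minimal (cost {1, 10}; hidden
size {4, 8}). All fits are single-threaded and seeded, so segmentation is
voxel-for-voxel reproducible.

**Masked prediction.** When a neurite mask is supplied only masked voxels
are predicted and everything outside is background, so the prediction is
always a subset of the mask; without a mask the whole volume is scanned.
An optional overlay volume (prediction outlines burned into the raw
channel) supports visual review.

## Quantification

Connected components of the binary prediction become puncta, by default
under 26-connectivity — the most permissive choice, so diagonal-touching
fragments of one synapse are not split; it is exposed (`connectivity`)
because 6-connectivity is the right choice when distinct puncta frequently
touch corner-to-corner. Each punctum carries voxel count, physical volume
(`voxels × prod(spacing)`), and mean/max/total intensity from the synapse
channel.

Positions along the neurite use an SWC skeleton: each punctum is assigned
its Euclidean-nearest node (ties resolved toward the soma for
determinism), and its normalized position is the node's arc length divided
by total neurite length — 0 at the soma, 1 at the furthest terminal — or
rescaled over the synapse domain (the occupied arc span, whose extremes
map to exactly 0 and 1). Puncta at least as large as a radius-10 sphere
(the diffuse-signal boundary, ~4189 voxels, configurable) are instead
spread voxel-by-voxel over their nearest nodes, which smooths the profile
of large unresolved signals. Population profiles pool all worms and weight
positions by voxel counts; the histogram is divided by total pooled
synaptic volume times bin width, so it integrates to exactly 1. Pooling
(rather than averaging per-worm densities) weights each worm by its
synaptic volume; per-worm profiles remain available via
`puncta_positions()` for the averaging variant. Per-image summaries report
the synapse-domain length and count/volume densities over it; a
single-punctum image has domain length 0 and `NA` densities rather than
an infinity.

Anisotropic voxel spacing is honored in nearest-node distances, arc
lengths and volumes. If no spacing metadata is supplied, 1 µm isotropic is
assumed with a warning and densities are per voxel-unit.

## Evaluation

`compute_iou` defines empty-vs-empty as 1 (perfect agreement on absence).
`benchmark_training_size` trains on every combination of each training-set
size (seeded subsample above `cap = 50` combinations) and reports held-out
IoU per image then averaged, with the pooled-voxel variant alongside.
Inside the benchmark, grid search is off by default so hyperparameters are
constant across sizes and the curve isolates the effect of training-set
size. `compare_annotators` reports the pairwise IoU matrix and its mean
off-diagonal as the inter-annotator benchmark.

## The synthetic generator

Every stage is testable without microscopy data through
`synthetic_spec()` / `generate_sample()`: a smooth seeded polyline spans
the volume, the neurite is its radius-3 tube (cytoplasmic channel at +150
over a background of 100), puncta are isotropic Gaussian blobs
(`σ = radius/2`) centered on neurite voxels with non-overlap enforced
(center gap ≥ r₁+r₂+1), clutter blobs with the same intensity model are
placed at least two tube radii off the neurite to stand in for tissue
autofluorescence, and i.i.d. Gaussian noise is added. Ground truth is the
noiseless blob support above half peak (apparent radius ≈ 0.59·r; a
radius-1 punctum keeps at least its center voxel). The four presets span
the regimes punctate reporters produce: small puncta (radius 1–3 voxels)
at low (peak 60, noise 20) or high (peak 200) SNR, medium (3–10), and
diffuse (>10) signal; 20 puncta and 10 clutter blobs in a 16×128×128
stack for the small presets. Real reporters are not characterized by
published SNR figures, so the preset intensities are calibrated only to
be qualitatively plausible; no claim is made of matching any particular
strain.

What passing tests on this generator show: the mechanics are correct —
masking strictly bounds predictions and removes off-neurite false
positives, one labeled image suffices to recover puncta counts within 10%
on held-out samples, the second layer does not degrade pixel F1, profiles
of uniformly placed puncta are flat. What they do not show: performance on
real tissue, where background is structured rather than i.i.d., puncta
are not Gaussian, neurites branch and cross, and annotation itself is
noisy. The clutter-rejection benchmark is run with the classifier seeing
only the synapse channel; with a cytoplasmic channel among the features
the classifier itself learns to reject off-neurite signal and masking
contributes little on synthetic data — on real data both mechanisms are
useful because the cytoplasmic channel is often dim or absent.

## Numerical conventions

Volumes are `(z, y, x)` arrays with 1-based voxel indices; physical
positions are `index × spacing` µm. Filters reflect at boundaries, so a
constant image has exactly zero derivative features. Labels are stored as
uint8 0/255 TIFF and any nonzero voxel reads as true, tolerating labels
drawn with external annotation tools; images are 16-bit TIFF, so integer
intensities round-trip exactly. All stochastic steps (placement, sampling,
initialization, augmentation, forest fitting) consume explicit seeds;
classifier fits and predictions run single-threaded, making every pipeline
output reproducible bit-for-bit under a fixed seed.
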