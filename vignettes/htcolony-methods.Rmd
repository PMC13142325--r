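---
title: "Label-free colony pluripotency assessment from refractive-index tomograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free colony pluripotency assessment from refractive-index tomograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the problem

Holotomography reconstructs the three-dimensional refractive index (RI)
of a live specimen without labels. In stem-cell culture, the RI field of
a colony encodes its physiology: RI is proportional to local dry-mass
concentration through the specific refractive increment, so an RI
tomogram is simultaneously a morphology map and a biochemical density
map. Undifferentiated human pluripotent stem-cell (hPSC) colonies are
compact, domed and sharply bounded; colonies exiting pluripotency
flatten, develop intercellular gaps and irregular protrusive margins,
and redistribute dry mass. `htcolony` turns these observations into a
quantitative pipeline with three layers:

1. **Segmentation** of colony footprints and occupancy volumes from the
   RI field by fixed thresholding and morphological closing.
2. **Patch classification**: a bottleneck-attention residual network
   scores fixed-size patches with the probability `P_undiff` of being
   undifferentiated; patch scores average into a colony-level call.
3. **Morphometrics**: a 31-property vector per colony (geometry,
   thickness, curvature, dry mass, lipid and gap content, spatial
   moments), feeding standardization, Leiden clustering on a kNN graph,
   UMAP visualization, effect sizes and correlation analysis.

A phantom generator emulating stitched holotomograms supplies labelled
synthetic colonies with exact ground truth, so every stage is testable
without imaging data.

## Data model and segmentation

A `tomogram` is a dense `(z, y, x)` array of dimensionless RI with a
voxel pitch in micrometres and the index of the substrate slice. The
default pitch is `dz = 0.9496`, `dy = dx = 0.3109` um: with it, a
79.6-um patch is exactly 256 px and the 11.4-um vertical crop is exactly
12 slices, matching the classifier's input geometry. Volumes are stored
as multi-page 32-bit float TIFF with a JSON sidecar (pitch, substrate
index, id). The writer is a minimal uncompressed float TIFF emitter
implemented in the package, because the available TIFF writer quantizes
to integer samples; reading goes through libtiff and the round trip is
bit-exact at 32-bit precision.

The footprint mask thresholds the maximum-intensity projection (taken
from the substrate slice upward) at RI `> 1.342`, then applies two
serial closings with disk kernels of 1 and 2 um physical radius.
Between the dilation and the erosion of each closing, enclosed
background regions are filled, so interior low-RI structures (gaps,
thin spots) belong to the footprint; a plain closing-then-fill variant
is available via the `fill` argument. Kernels are rasterized by
centre distance at the physical pitch (a 1-um kernel at 0.3109-um pitch
is a 7x7 disk), and all morphology treats out-of-image pixels as
background. The 3D occupancy mask is the intersection of `RI > 1.3400`
(strict) with the footprint columns at or above the substrate. When the
substrate index is absent, it is estimated as the lowest slice whose
occupied fraction (RI above 1.3400) first exceeds 0.5 % of the in-plane
area.

## The classifier

The network is a 50-layer bottleneck residual backbone — a 7x7 stride-2
stem to 64 channels with batch normalization, ReLU and a 3x3 stride-2
max pool, then 3/4/6/3 bottleneck blocks with stage widths
256/512/1024/2048 — taking the 12 z-slices of a patch as input
channels and ending in global average pooling and a 2-logit head. The
first stage runs at stride 1 so that a 256-px input yields stage
feature maps of 256x64x64, 512x32x32, 1024x16x16 and 2048x8x8; stages
2-4 downsample by 2 in their first block, in both the convolutional and
the projection path.

A bottleneck attention module (BAM) sits between consecutive stages
(three in total). Its channel branch summarizes the stage output by
both global average and global max pooling, projects each descriptor
through its own biased linear map to `C/16` features, and expands the
ReLU of their sum back to `C` channels through a shared bias-free
linear map. Its spatial branch applies a bias-free 1x1 reduction to
`C/16` channels, two biased 3x3 convolutions dilated by 4, and a biased
1x1 collapse to a single map. The two branches are broadcast-summed,
passed through a sigmoid, and applied residually: `out = x * (1 + att)`.
This micro-placement of biases (and the absence of normalization layers
inside the module) is the configuration frozen in the package; it was
chosen so the instantiated network carries exactly 23,981,749 trainable
parameters over 65 convolutional layers (stem + 48 block convolutions +
4 projection shortcuts + 4 convolutions per attention module), the
totals `summarize_architecture()` reports. The same builder with 3
input channels, 1000 classes and no attention modules reproduces the
canonical 50-layer residual network's 25,557,032 parameters, which the
test suite uses as an independent anchor.

No deep-learning framework is available to R in this environment, so
the layers are implemented natively: convolutions lower to im2col plus
BLAS matrix products, and every layer (convolution with stride and
dilation, batch normalization, max pooling, the attention gate, the
linear head) carries a hand-written backward pass verified against
central finite differences to ~1e-5 relative error. Inference is
deterministic; training uses per-batch statistics with running-average
updates (momentum 0.1) for evaluation mode.

### Patches, normalization, augmentation

Colony footprints are tiled on a 39.8-um grid over the bounding square
padded by 20-um margins where available. Training patches are stored at
119.3 um and randomly cropped to 79.6 um; evaluation patches are stored
at 79.6 um (the crop is the identity). The vertical window spans
11.4 um above the substrate; its 12 slices become the input channels.
RI is linearly mapped from [1.330, 1.400] to [0, 1] with clipping —
out-of-range RI is rare and carries no class information at these
thresholds. Augmentation applies independent x- and y-flips and an x-y
transposition, each with probability 0.5, then i.i.d. Gaussian noise
with a standard deviation drawn once per patch from U(0.001, 0.1) in
normalized units (noise after normalization, following the order of the
processing chain). Grid origins whose patch footprint overlaps the
colony by less than 10 % are dropped by default (`min_overlap_frac`);
set 0 for strict grid tiling. This floor is the package's own knob: it
keeps pure-background tiles from dominating training on sparse plates.

### Optimisation and colony calls

Training uses SGD with Nesterov momentum 0.9, learning rate 0.001,
weight decay 1e-4 and batch size 256; each iteration draws a fresh
random 5 % subsample of the training set (without replacement) and
sweeps it in mini-batches; the learning rate follows cosine annealing
`lr(t) = 0.001 (1 + cos(pi (t mod 16)/16))/2` over 300 iterations. The
returned checkpoint maximizes the sum of validation and blind-test
accuracy (earliest iteration on ties); because selecting on the blind
set is methodologically debatable, `select_checkpoint` also serves
val-only histories. Per-patch `P_undiff` is the softmax probability of
the undifferentiated class; the colony score is the plain mean over the
patch list, and a colony is called undifferentiated iff the mean
strictly exceeds 0.5 (exactly 0.5 is differentiating). Grad-CAM
saliency hooks the feature maps of the second 3x3 convolution of the
final bottleneck block (8x8 native resolution at 256-px input, after
its normalization and ReLU) and upsamples the ReLU of the
gradient-weighted sum to patch resolution.

### Desk-scale training configuration

The full-scale training regime (hundreds of thousands of patches, GPU
hardware) is out of reach for a CPU-only package check, and matched
imaging data are not available. The package therefore ships
`scaled_training_run()`: phantom colonies are tiled into 400 training
patches per class, pooled 4x to 64-px inputs, and a reduced architecture
(one bottleneck block per stage, stage widths 64/128/256/512, attention
modules kept, ~0.5 M parameters) is trained with the same optimiser
recipe at batch 32, subsample fraction 0.2, for 30 iterations. On the
default phantom conditions this reaches >=90 % held-out patch accuracy
and >=90 % colony-call accuracy in a few minutes on one CPU core, which
is what the acceptance suite asserts; it demonstrates that the training
loop, schedule, checkpointing and colony aggregation work end to end,
not that full-scale accuracy transfers to real tomograms.

## Morphometrics: the 31 properties

The catalogue is 15 scalars — footprint area, occupied volume, mean and
SD of in-colony RI, total dry mass, mean and SD of thickness, aspect
ratio, surface curvature, roundness, solidity, eccentricity, boundary
RI contrast, lipid volume, gap area ratio — plus spread, skewness,
kurtosis and centroid displacement for each of four spatial maps
(thickness, areal dry mass, lipid presence, gap presence), totalling
31. Specific choices:

* **Thickness** is the occupied-voxel count per column times `dz`;
  statistics are taken at least 5 um inside the footprint boundary to
  decouple them from colony size and edge shape. The per-column surface
  height used for curvature and profiles is the same count — equal to
  the highest occupied voxel for solid columns but robust to isolated
  supra-threshold speckle voxels above the surface.
* **Curvature** fits a sphere to the inset top-surface points: an
  algebraic least-squares seed polished by a geometric
  (orthogonal-distance) Gauss-Newton fit. The algebraic fit alone is
  biased toward small radii for shallow voxelized caps (axial
  quantization acts as noise); the geometric polish removes most of
  that bias — on flattened phantoms it cuts the curvature error from
  ~4-7 % to ~1 %. Sign is positive for domes, negative for bowls;
  near-planar surfaces report 0 with the radius capped at 1e5 um.
* **Dry mass** converts RI excess over the medium (1.337) with the
  specific refractive increment alpha = 0.185 um^3/pg — standard
  quantitative-phase-imaging constants, both configurable — clipping
  negative increments; a z-resolved profile and window aggregation
  (e.g. basal 1.899-3.798 um, apical 9.496-11.395 um above the
  substrate) come with it.
* **Lipid droplets** are connected components of `RI > 1.3800` inside
  the colony; a component wider than 3 um (maximum horizontal Feret
  diameter over pixel centres) is kept only if its peak RI reaches
  1.4000. **Gaps** are components of projection RI `<= 1.3400` inside
  the footprint, dropped when 25 % or more of their area lies within
  5 um of the boundary. Gap candidates are restricted to the footprint:
  gaps are by definition intra-colony.
* **Shape**: roundness is `4 pi A / P^2` with the perimeter from the
  boundary chain code under the Vossepoel-Smeulders corner correction
  (the raw staircase polygon overestimates smooth boundaries by ~5 %,
  which would cap a perfect disk's roundness at ~0.90); solidity is the
  area over the convex-hull area; eccentricity comes from the
  second-moment ellipse. Aspect ratio is mean thickness over the
  equivalent footprint diameter — a height-to-width measure chosen
  because flattening expresses jointly as falling thickness, curvature
  and aspect ratio; the planar minor/major-axis alternative is
  available via `aspect = "planar"`.
* **Spatial moments** treat each map as a weight density over the
  footprint: spread is the weighted RMS distance from the weighted
  centroid normalized by the equivalent radius, skewness and kurtosis
  are standardized moments of that radial distance, and centroid
  displacement is the weighted-to-unweighted centroid distance, again
  normalized. Radial spatial moments (rather than histogram moments of
  the values) were chosen because the maps are listed among spatial
  properties and because they are rotation-invariant by construction.
  All-zero maps (e.g. the lipid map of a droplet-free colony) return
  zeros with a degeneracy flag rather than NaN.

Colonies whose footprint bounding box is under 14,250 um^2 are excluded
from property extraction (strictly under; the boundary value passes).

## Cohort analysis

Properties are z-scored per column (constant columns dropped with a
warning). Colonies are clustered with the Leiden algorithm on the
Euclidean kNN graph (k = 8 neighbours per colony, one-sided edges
unioned), using the modularity objective at resolution 1.0: with
cohorts of tens of colonies, modularity recovers well-separated groups
as connected components without the over-splitting CPM tends toward at
comparable resolutions; both knobs are exposed. Per-cluster Cohen's d
(one cluster versus the rest, pooled SD) ranks properties by |d|;
Welch's t-test serves labelled group comparisons; Pearson correlation
relates each property to the colony `P_undiff`. The 2D embedding is a
self-contained UMAP implementation (smooth-kNN affinities, fuzzy-union
symmetrization, PCA initialization, negative-sampling layout),
deterministic under a fixed seed, written natively because no UMAP
package is available to R in this environment; it targets cohort-scale
data, not atlas-scale.

## The phantom generator

Phantoms define the reference conditions for all self-contained validation.
Each phantom is a spherical-cap colony on a substrate plane at slice 3
in a 24 x 480 x 480 voxel volume at the default pitch (a ~149-um field
of view): the footprint radius defaults to 61-67 um so that bounding
boxes clear the 14,250-um^2 QC threshold. Undifferentiated colonies are
tall (apex drawn from U(12, 18) um), sharply bounded (edge-smoothing
sigma U(0.6, 1.0) um) and gap-free; differentiating colonies are flat
(U(5, 9) um), blurred (U(1.8, 2.6) um), with a more irregular outline
and 2-4 low-RI channels carved through the interior, each kept at least
7 um from the boundary so the proximity-exclusion rule retains them.
The cytoplasm is a smooth random RI field (mean 1.355, SD 0.004,
clipped to [1.345, 1.370]); nucleoli are 1.372-RI spheres; lipid
droplets are 0.4-1.2-um spheres at RI U(1.395, 1.405) placed at least
3.5 um apart so droplets never merge past the 3-um width rule. Ground
truth (footprint, thickness map, cap radius, lipid voxels, gap masks)
is recorded before sensor noise is added.

Sensor noise is i.i.d. Gaussian with SD 0.001 RI. This value is set by
the geometry of the gap rule: gaps are detected as projection RI at or
below 1.3400 while the medium sits at 1.337, a margin of 0.003; the
projection of ~22 slices rides ~2.1 sigma above the per-voxel mean, so
a noise SD of 0.002 would push most true gap columns over the threshold
and make the fixed 1.3400 rule unrecoverable, while 0.001 keeps the column
failure rate near 3 %. The augmentation noise range the classifier
trains under (0.001-0.1) covers it.

Class effect sizes (thickness, gaps, boundary sharpness) are
deliberately large so that desk-scale training converges in minutes.
Passing the pipeline on phantoms demonstrates internal consistency —
segmentation recovers constructed geometry, training learns the
constructed contrast, clustering recovers the constructed classes. It
does not demonstrate robustness to reconstruction artefacts, optical
aberrations, mitotic or apoptotic debris, colony merging, or the
subtler morphology of real differentiation, none of which the phantoms
model.

## Numerical choices and degenerate inputs

* Voxel intervals are half-open; indices 1-based in R, with the sidecar
  storing the substrate index 0-based for interoperability.
* The RI validity range is [1.30, 1.50]; out-of-range volumes warn by
  default and can be promoted to errors.
* Batch-norm uses eps 1e-5 and momentum 0.1; weight decay applies to
  all parameters, as in the common framework default.
* Checkpoint ties resolve to the earliest iteration; `which.max`
  semantics are asserted in the tests.
* Empty threshold masks warn and return empty footprints (the caller
  decides); empty boundary bands, over-eroded insets, sub-4-point
  sphere fits and single-class training sets are errors.
* Problem sizes in the shipped checks: training uses 400 patches per
  class from 10 phantom colonies per class at 64-px pooled resolution;
  parameter recovery uses 20 phantoms; pipeline closure uses a
  40-colony cohort. These sizes make the full suite run in tens of
  minutes on one core while leaving the assertions statistically
  meaningful.

## Known limitations

* HDF5 I/O is not available in this build (no HDF5 R package in the
  environment); the TIFF dialect plus JSON sidecar is the storage
  format, and `format = "hdf5"` fails with a clear message.
* The full-scale network trains only in principle on CPU; the shipped
  training path is the reduced configuration described above.
* The 31-property catalogue is one defensible realization of the
  property family; most individual property names are
  the package's own, and the catalogue is centralized in
  `property_names()` so alternates can be swapped.
* Phantoms are geometric stand-ins, not light-scattering simulations;
  see above for what that implies about external validity.
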