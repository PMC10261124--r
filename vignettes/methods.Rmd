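---
title: "Methods: vector-field instance splitting of 3D nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vector-field instance splitting of 3D nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Nuclei in cleared-tissue 3D fluorescence microscopy are densely packed and
axially elongated by the point-spread function; touching nuclei form a
single foreground component, so semantic segmentation alone cannot count
or delineate them. `nucsplit3d` attacks the problem with a per-voxel
*centroid-offset vector field*: every foreground voxel stores the 3D
offset to the centroid of the nucleus that owns it, and background voxels
store the exact zero vector. Ownership — not metric nearness — defines the
target, so the field is well defined even for interleaved shapes; this
matters only for pathological geometries, and for convex nuclei the two
readings coincide. Centroids are kept sub-voxel (no rounding): rounding
would inject quantization ridges into the gradient map downstream.

Two properties make this field useful. First, within one nucleus the
vectors converge on a single point, so the axis-wise derivative of each
component is negative in the interior. Second, across the interface
between two touching nuclei the field flips from pointing one way to
pointing the other, producing a large *positive* derivative exactly on the
interface. The package therefore differentiates each field component along
its own axis with an unnormalized 3D Sobel stencil (derivative `[-1,0,1]`
on the own axis, smoothing `[1,2,1]` on the other two; reflected
boundary), and takes the elementwise *signed* maximum of the three
responses as the gradient map `G`. The signed form is deliberate: interior
responses are negative and interface responses positive, so a single
threshold `T_m` separates them; an `abs_gradient` option is provided for
users who prefer the magnitude convention.

## Instance splitting

Given a foreground mask (probabilities are binarized at 0.5) and a vector
field, `segment_instances()` composes:

1. **Carving**: `blob = relu(mask − (G ≥ T_m))` removes interface voxels,
   usually disconnecting touching nuclei. The unnormalized Sobel kernels
   scale a per-voxel component jump of 1 to a response of ~16, so `T_m`
   lives on that scale; the desk preset uses `T_m = 64` (a 4-voxel jump),
   calibrated on the package's own synthetic volumes with semi-axes 4–8
   voxels. Presets for the five benchmark volume regimes are in
   `seg_preset()`.
2. **Conditional erosion**: 26-connected components of the blob are
   iteratively eroded — with the coarse element `B_c` while their size is
   at least `t_c`, then with the fine element `B_f` while at least `t_f` —
   re-splitting into components after every pass and recursing into each
   piece. A component that an erosion would annihilate keeps its last
   nonempty state, so no nucleus loses its marker. The default elements
   are a 5×5×3 discrete ellipsoid (coarser axially, matching the coarser
   axial sampling of confocal stacks) and the 3×3×3 six-connected cross;
   both are user-overridable, as only their qualitative shape is
   specified by the approach.
3. **Marker-controlled watershed**: basins flood from the markers over the
   negative Euclidean distance transform of the mask, restricted to the
   mask, so every foreground voxel receives exactly one label. The
   elevation choice is the standard one for marker-controlled practice;
   an optional blend with inverted smoothed intensity (`elevation =
   "blend"`, weight `w`) is provided since the original formulation names
   the intensity volume as an input without fixing its role. Foreground
   components containing no marker are kept as single new instances
   rather than discarded.
4. **Cleanup**: instances smaller than 20 voxels are removed and labels
   compacted.

The compiled primitives behind steps 2–3 (26-connected labeling, the
Felzenszwalb–Huttenlocher squared distance transform, and a priority-queue
seeded watershed with FIFO tie-breaking for determinism) are in `src/`.

## The multi-task network

`nn_unet3d()` builds an encoder–decoder with, per level, a 3×3×3
convolution block (convolution, batch normalization, leaky ReLU with
slope 0.1) and a residual block; downsampling is by stride-2 convolution
blocks rather than pooling. The decoder mirrors with transpose-convolution
blocks (zero-stuffing upsample + convolution block), additive
attention-gated skip concatenation, and convolution blocks. Two heads
share the trunk: a single-channel logistic mask head (binarized at 0.5)
and a linear 3-channel vector head — deliberately without any squashing,
because offsets are unbounded signed quantities. The attention gate maps
skip and gating features through 1×1 convolutions to `C/2` channels, adds,
rectifies, and squashes to a scalar gate per voxel; the published diagrams
leave the gate arithmetic unspecified numerically, so this standard
additive form was chosen.

The loss is `λ_TL·L_Tversky + λ_FL·L_focal + λ_MSE·L_MSE` with defaults
λ = (1, 10, 10). The Tversky term is `1 − TI` (with ε = 1e−6 smoothing);
the index itself is maximal at perfect overlap, so minimizing `1 − TI` is
the only coherent reading. Its weights α_FN = 0.3, α_FP = 0.7 trade missed
voxels against false voxels. The focal term uses β = 0.8, γ = 2 with
probabilities clipped at 1e−7; subscript conventions are taken with
"channel 1 = nucleus" on both target and prediction, the only
self-consistent assignment. The MSE term averages over all voxels × 3
components. Training uses Adam at a constant learning rate; the vector
target is computed from the labels with `generate_vector_field()` and the
mask target is `labels > 0`. Intensities are min–max normalized per
volume.

Two initialization choices, both standard practice, matter at desk scale:
the mask-head bias starts at the prior logit of an expected ~5% foreground
fraction (the usual remedy for class-imbalanced focal training), and the
closing batch-norm gain of each residual block starts at zero so every
block begins as the identity. With these, a 3-level, width-8 model
(~126k parameters) halves its combined loss and reaches mask IoU above
0.8 when overfitting a single 32³ patch for 50 epochs at learning rate
0.015, and reaches mF1 = 100 at IoU 0.25 on a held-out volume after 30
epochs on eight 32³ volumes — both checks run in the test suite. The
default learning rate of `train_unet3d()` remains 0.001, the conventional
setting for full-scale training; 0.015 is the documented desk-scale
setting used by the smoke tests, where only tens of gradient steps are
available.

The network is implemented natively in R: feature maps are
(voxels × channels) matrices and each 3×3×3 convolution is evaluated as 27
shifted matrix products, so the arithmetic runs in BLAS; gradients are
hand-derived per layer and verified against numerical differentiation in
the test suite. Batch statistics are frozen (running averages, momentum
0.1) in evaluation mode, so prediction is deterministic.

## Synthetic volumes

`place_nuclei()` draws ellipsoids with semi-axes independently uniform on
`[a_min, a_max]`, rotation angles uniform on `[0, 2π)` (Euler order X, Y,
Z, applied about the ellipsoid's own center before placement — rotating
about the global origin would distort the intended uniform placement
statistics), and centers uniform over the volume. A voxel belongs to an
ellipsoid when its body-frame coordinates satisfy the strict inequality
`(x/a_x)² + (y/a_y)² + (z/a_z)² < 1`. A candidate is accepted when at most
`t_ov` of its voxels are already occupied; contested voxels keep the
earlier label (first-come priority), which keeps every accepted instance's
ground-truth extent well defined, and `t_ov` is measured on the
pre-priority rasterizations. After 100 rejections a nucleus is skipped
with a warning, preventing nontermination at high densities. Four presets
(`v1`–`v4`) cover the sparse-to-dense regimes: (a 4–8, t_ov 5, N 500,
d 10, σ 1), (10–14, 10, 70, 4, 1), (6–10, 200, 200, 5, 2) and (8–10, 100,
560, 4, 4), all on 128³ volumes.

Elastic deformation draws a coarse `d×d×d×3` displacement field of i.i.d.
N(0, σ²) entries anchored at equally spaced positions spanning the volume
and interpolates each component to the full grid with natural cubic
splines; interpolation is linear in the anchors, so it is implemented as a
precomputed basis-matrix product per axis. Warping is *backward* with
nearest-neighbor sampling — the forward reading ("shift voxel p by d(p)")
leaves holes in label images, and for fields this smooth the two coincide
to within the sampling grid. A label split into several components by
warping keeps its single identity: instance identity follows the label,
not connectivity. σ = 0 reproduces the input exactly.

The renderer is a declared stand-in for generative texture synthesis: it
paints each instance at a jittered brightness, applies an anisotropic
Gaussian blur (axial σ twice lateral, mimicking the elongated confocal
point-spread function), adds background, Gaussian or Poisson–Gaussian
noise, and quantizes to 8 or 16 bits. It reproduces the statistical
structure the pipeline needs to be exercised — blurred blobs, axial
elongation, shot noise — but not real microscopy texture, intensity
inhomogeneity, or autofluorescent clutter. Passing tests on these volumes
therefore demonstrate the correctness of the machinery, not
state-of-the-art accuracy on real tissue.

## Tiled inference

`plan_tiles()` slides K-voxel windows at stride K/2 and pads each window
by K/4 per border; reflection supplies out-of-volume voxels. Only the
centered K/2 interior of each window is written to the output. The
centered-interior rule alone would leave the outer K/4 shell and trailing
remainders uncovered, so boundary-tile interiors extend to the volume
edges and trailing windows clamp to end at the edge, the interiors
absorbing the remainder — the only coverage-preserving completion.
Interiors are pairwise disjoint and cover every voxel exactly once, so any
operator whose output at a voxel depends only on inputs within Chebyshev
radius K/4 tiles exactly; the suite verifies bit-equality for a 3×3×3 mean
filter on a 256×256×64 volume at K = 128. Instance splitting runs once,
globally, on the stitched mask and field — per-tile splitting would cut
nuclei at seams.

## Evaluation

Detected and ground-truth instances are matched one-to-one, greedily in
descending IoU among pairs at or above each threshold t (an exhaustive
optimal-assignment mode exists and agrees with greedy matching on all
small fixtures, as the suite checks). Per threshold: precision, recall,
F1, and `AP_t = TP/(TP+FP+FN)`; label maps carry no confidence ranking
from which to trace a precision–recall curve, so this set-based AP — the
convention of the 3D nuclei-segmentation literature — is the default, and
a curve-based AP would require per-instance scores. The aggregates mP, mR,
mF1, mAP average over the threshold set (default {0.25, …, 0.45}; a
{0.5, …, 0.75} preset suits easier data) on the 0–100 scale. The
Aggregated Jaccard Index accumulates, over ground-truth instances in label
order, the best-unused-prediction intersection and union, then adds
unmatched predicted volume to the denominator — intersection over union,
the convention that keeps AJI within [0, 1]. Two boundary conventions are
explicit: an empty prediction against empty ground truth scores perfect
(with a logged notice), and an empty prediction against nonempty ground
truth guards precision to 0.

## Numerical choices and problem sizes

Vector fields satisfy `voxel + vector = centroid` to one double rounding
(the subtraction is performed once and is bit-reproducible; the re-added
identity can differ by one ulp). TIFF storage: integer volumes round-trip
bit-exactly at 8/16/32-bit unsigned depth (labels must fit a signed
32-bit integer); vector fields are stored as 3-sample pages affinely
mapped into [0, 1] by a scale derived from the volume diagonal — offsets
are bounded by the diagonal, so the mapping is self-describing — and
round-trip to within single-precision resolution. Right-angle rotation
matrices are snapped to exact 0/±1 entries so boundary voxels do not flip
across the strict rasterization inequality.

The test suite and acceptance script run at desk scale, chosen so the
whole suite completes on one CPU: 20 volumes of 64³ for vector-field
exactness, 20 of 96³ (N = 40) for oracle-mode recovery, 256×256×64 for
tiling equivalence, and 32³ patches for the training smoke runs. Known
limitations: no multi-lobed or clustered nucleus models, no GAN-quality
textures, isotropic distance in the watershed elevation, and training at
realistic scale (hundreds of 128³ volumes, 100 epochs) is out of reach of
a pure-R implementation — the architecture and losses are exercised at
reduced size instead.
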