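---
title: "Methods: synthetic ground truth, segmentation, morphometry and motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ground truth, segmentation, morphometry and motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and numerical choices behind the package:
what each stage computes, which parameters matter, what the synthetic data
generator does and does not emulate, and where the design was genuinely open.

## The problem

Volume electron microscopy of tumour tissue produces aligned 3D stacks at
strongly anisotropic sampling — about 5 nm laterally and 50 nm between
sections.  Mapping mitochondrial networks in such volumes requires
(i) segmenting nucleus and mitochondria from the background, (ii) splitting
the mitochondrial mask into instances, (iii) measuring each instance's size
and shape, (iv) relating each instance to the nucleus and to lipid droplets,
and, from live-cell fluorescence, (v) quantifying how motile the network is.
Each stage here is a tested function; the stages chain through
`run_pipeline()` or the numbered scripts under `analysis/`.

All voxel data use `(z, y, x)` axis order, 0-based voxel indices and
nanometres internally; tables report micrometres.  Every source of
randomness is an explicit seed; no stage reads the clock.

## Synthetic ground truth

`generate_cell_volume()` rasterizes a parametric cell: an ellipsoidal
nucleus, capsule-shaped mitochondria (tube radius 100 nm by default) whose
axes are smoothed 3D random walks, and spherical lipid droplets.  Axis
lengths are log-normal with arithmetic mean/sd given in µm; the
`"elongated"` preset (mean 1.2 µm, sd 0.4 µm) and the `"fragmented"` preset
(0.4 ± 0.15 µm) emulate the two network phenotypes seen in oxidative versus
glycolytic tumour cells, without hard-coding a phenotype cutoff — no
quantitative fragmented/elongated boundary is established in this field, so
the length distribution is the exposed knob.  Placement is either uniform over the cytoplasm or confined to
a perinuclear shell (default width 1 µm).  Instances are placed by rejection
sampling with a hard cap (default 1,000 tries per instance) and a clearance
margin of 2.5 section-steps' worth of nm beyond the radius, so planted
instances are never 26-connected and a median filter cannot bridge them — which is what makes "instance count
recovered exactly" a meaningful downstream check.  A configurable fraction
of mitochondria (`pdm_fraction`) is instead planted in genuine
droplet contact: the capsule axis is translated so its closest approach to a
chosen droplet realizes a surface gap sampled within 5–35 nm, approached in
the imaging plane where the 5 nm pixel pitch resolves the gap (an approach
along the 50 nm section axis could not be quantified reliably).

Grayscale is per-class mean intensity plus i.i.d. Gaussian noise
(EM-like: dark organelles on a bright background, brighter lipid), not
clamped, so the stated noise model holds exactly.  The generator does *not*
emulate membrane texture, cristae, staining gradients or section-alignment
artifacts; tests passing on these scenes show the measurement chain is
correct, not that the network would reach any particular accuracy on real
tissue.

The motility generator translates a reference mask by `velocity × (n−1)`
pixels per frame (rounded), 10 frames at 20 s by default, failing loudly if
the object leaves the field.

## Segmentation

**Network.**  `net_config()` encodes the architecture: five residual encoder
stages (32, 64, 128, 256, 256 filters), max-pooling after the first three
stages only so the deepest feature maps sit at 1/8 of the input resolution
(96×96 for a 768×768 input), an atrous spatial pyramid pooling block with
dilation rates 6, 12, 18, 24 at the bottleneck, and a decoder that such
recipes leave unspecified beyond "based on U-Net" — here three
nearest-neighbour upsampling stages, each concatenating the matching encoder
resolution and applying two 3×3 convolutions.  The residual block is
conv–lrelu–conv plus a learned 1×1 projection of the input; ASPP branches
are summed.  The leaky-rectifier slope (unstated in the recipe) defaults
to 0.01.  Initialization (also unstated beyond "random uniform") is fan-in
scaled uniform with zero biases.  Forward and backward passes are
shifted-matmul convolutions on Armadillo cubes, exact gradients verified
against finite differences in the test suite.

**Training.** `train_config()` defaults to the full-scale recipe: per-pixel
cross-entropy, Adam (β₁ = 0.9, β₂ = 0.999), learning rate 1e-4 stepping to
1e-5 after epoch 150 of 200, batch size 8, and five augmentations
(horizontal/vertical flips, rotations in [−20°, 20°], zero-mean Gaussian
noise with sd 0.08, random crops down to 90 % of height/width), each applied
independently with probability 0.5; geometric transforms use bilinear
resampling for images and nearest-neighbour for labels, and the stored
transform record reapplies to a label exactly.  The desk-scale sanity runs
in the tests and `analysis/07` use four 128×128 images, filter widths
8–64, 60 epochs, batch size 1 and a learning rate of 2e-3 stepping to
5e-4 — batch size and rate rescaled together so the run sees enough
optimizer steps to overfit on a single CPU in under a minute; the point of
that run is only that the implementation can drive its training loss down
and reproduce its own training labels (macro-DICE ≥ 0.9).

**Metrics.**  One-vs-rest confusion counts per foreground class give DICE,
IoU (Jaccard), precision and recall; the macro average is over the two
foreground classes, and a pixel-pooled (micro) variant is also computed
because published figures do not always say which was used.  A class absent
from both maps scores 1 by convention so macro averages stay defined on
sparse tiles.

**Classical pipeline.**  `classical_instance_segmentation()` mirrors the
interactive workflow used for whole-cell labelling: 3×3×3 median filter,
optional percentile contrast rescaling, threshold (Otsu on the filtered
histogram by default — the interactive threshold of the original workflow
is replaced by an optional fixed value), optional marker-based watershed on
the anisotropy-aware distance transform to split touching objects, then 3D
connected components (26-connectivity by default, the bright-object
convention).

## Morphometry

Volume is exact: voxel count × physical voxel volume.  Surface area comes
from an isosurface mesh because voxel-face counting overestimates area by
~50 % and destroys the Ψ ≤ 1 property: each instance crop is resampled
trilinearly onto an exactly isotropic grid (step h = max(native pixel,
r_eq/10) with r_eq the volume-equivalent radius, capped at ~3×10⁶ samples),
smoothed with a separable Gaussian of σ = 0.8 samples, and meshed by
marching tetrahedra at the 0.5 level.  The smoothing width was calibrated
once against the analytic sphere — on a radius-20 ball the meshed area is
within ~0.5 % of 4πr², giving sphericity ≈ 0.995 — and the same setting
makes Ψ decrease strictly along an elongating capsule family.  Padding
guarantees a zero border thicker than h so the mesh always closes.

Length has no standard definition for curved tubules; here it is the
geodesic diameter of the instance: two Dijkstra sweeps over the
26-connected voxel graph with physical edge lengths find the farthest
voxel pair, and the connecting path is straightened by averaging its voxels
into blocks of roughly r_eq arc length and summing chords between block
centroids — the averaging cancels the transverse zig-zag that grid paths
acquire at 10× z-anisotropy.  On straight capsules this recovers axis
length + 2r within a few per cent; a principal-axis extent is available as
an alternative (`length_method = "major_axis"`).  A thinning-based skeleton
was considered and rejected: it adds a large algorithmic surface for no
gain at these shapes, since the geodesic diameter of a tube equals its
skeleton length plus the two end caps.  Single-voxel instances get total
measures (box area, longest voxel edge) rather than NaNs.

## Nucleus distances

In fluorescence images the nucleus is fitted as the moment-equivalent
ellipse of its mask (centroid; semi-axes 2√eigenvalue of the second central
moments; tilt from the leading eigenvector).  The minimum distance from a
mitochondrion centre to that ellipse solves a constrained optimization with
Lagrange multipliers: in the standard frame the stationarity condition
reduces to the quartic

(c y + b²v)²(y² − b²) + u²a²b²y² = 0,  c = a² − b²,

whose real roots (companion-matrix eigenvalues, imaginary parts ≤ 1e-9
filtered) give at most four candidate boundary points.  The abscissa is
recovered from the stationarity relation x = u a² y/(c y + b² v) rather
than from ±a√(1−y²/b²), which keeps one candidate per root (≤ 4 total) and
carries the correct sign; the best candidate is then polished by a few
safeguarded Newton steps on the parametric form, so the returned point
satisfies the implicit equation to machine precision.  Degenerate positions
are handled analytically: the centre maps to the minor-axis vertex (tie
broken toward +y), on-axis points check the vertices plus the off-axis
critical points that exist inside the evolute, and circles use the radial
closed form.  A dense-sampling + golden-section oracle
(`point_to_ellipse_distance_oracle()`) validates the solver to 1e-6
relative over randomized pairs.

In 3D, distances come from an exact anisotropy-aware squared Euclidean
distance transform (the two-parabola lower-envelope algorithm applied per
axis with physical spacings); per instance either the minimum over its
voxels ("surface", the default) or the value at its centroid voxel.
Distances are voxel-centre based, so a face-adjacent voxel reports one
pixel pitch, and anything inside the nucleus footprint reports 0.

## Motility

Frame 1 is the reference.  For each later frame, overlap_area is the pixel
count of the intersection with frame 1, travel_area is the frame's area
minus the overlap, and the displacement ratio is travel/overlap.  Frames
with zero overlap have no defined ratio; they are excluded from the
regression and recorded with a reason, rather than capped or imputed — the
imaging protocol does not define this case and exclusion preserves the
statistic's definition.  The readout is the ordinary least-squares slope of
ratio against time (s⁻¹).  Whether thresholds should be per-frame or shared
from frame 1 is unstated in the protocol; per-frame is the default and a
shared-threshold flag exists.  Background subtraction is a grayscale
opening with a disc (rolling-ball style), radius configurable.

## Compartments and phenotyping

Mitochondria partition into peri-droplet (PDM: minimum surface distance to
any lipid droplet ≤ 50 nm), perinuclear (PNM: minimum surface distance to
the nucleus ≤ 1 µm) and cytoplasmic (CM: neither).  The two cutoffs are not
specified numerically by the source study; the defaults are conventional
organelle contact-site and perinuclear scales, both configurable and echoed
into outputs.  A mitochondrion meeting both definitions is PDM — the three
groups are treated as exclusive and droplet contact is the more specific
physical event; the precedence order is itself a parameter.  A
mitochondrion touching several droplets is classified once (a label, not a
contact count).  Tracer phenotyping applies the tumour-to-heart uptake
ratio thresholds — ≥ 0.5 for the membrane-potential tracer, ≥ 0.2 for the
glucose tracer, boundaries inclusive — and `normalize_mrc()` divides
respiratory capacity by the mitochondrial-content signal.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problems chosen
as the smallest sizes at which each property is meaningfully exercised:
1,000 random ellipse pairs; one 768×768 forward pass at full filter widths;
a 64×512×512 scene with 20 planted capsules; a radius-20 ball; four-image
training at 128×128.  Scene generation, training and the full-width forward
pass each take well under a minute on one CPU.  Identical seeds give
bit-identical scenes, training runs and pipeline tables; `run_pipeline()`
writes a manifest with the config hash and package version alongside its
artifacts.

## Known limitations

* Published segmentation accuracies on real annotated SBEM slices (DICE of
  about 0.9) cannot be reproduced from synthetic scenes: they require the
  corresponding annotated training volumes.  The tests bound what this
  implementation can claim — architecture contract, gradient correctness,
  and overfit capacity.
* Surface area and length inherit an information limit from the 50 nm
  section step: structures thinner than about two sections are measured
  with the fidelity the resampling allows, no better.
* The motility statistic is field-of-view level (whole-mask areas), as its
  defining formulas are; no per-object tracking is attempted.
* Crista-level structure is out of scope entirely.
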