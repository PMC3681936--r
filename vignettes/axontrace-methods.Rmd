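---
title: "Reconstructing myelinated axons from serial sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing myelinated axons from serial sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axontrace)
```

## The problem

Semi-thin serial sections of a peripheral nerve, stained so that the myelin
sheath is dark and both the axonal lumen and the surrounding tissue are
bright, can be digitized into a z-ordered image stack and traced axon by
axon. Each myelinated axon appears on each section as a bright, roughly
circular lumen inside a dark ring. `axontrace` implements the full chain
from such a stack to quantitative morphometry and an export-ready 3D
surface model:

1. **Preprocessing** — grayscale conversion, cropping, physical calibration,
   and rigid (translate + rotate) slice-to-slice alignment.
2. **Segmentation** — seeded region growing ("wildfire") inside each lumen,
   propagated slice to slice, with every propagation failure logged as a
   *tracing abortion*. Abortions are the central segmentation-quality
   indicator: their rate per axon per slice responds to section spacing,
   axon caliber and image artifacts.
3. **Morphometry and QC** — per-slice inner cross-sectional areas,
   idealized diameters, area-fluctuation normalization and class
   comparisons, abortion-rate analyses.
4. **Mesh reconstruction** — lofting traced contours into watertight
   triangle meshes, volume-preserving HC Laplacian smoothing, quadric
   edge-collapse decimation, inter-axon overlap auditing, PLY/VRML export.

Because real histological stacks of this kind are rarely redistributable,
the package ships a first-class synthetic phantom generator with exact
ground truth; every downstream stage is tested against it.

## The phantom and what it emulates

`phantom_config()` describes a synthetic nerve: `n_axons` lumina packed
inside a circular nerve cross-section, each rendered per slice as a bright
disk (`lumen_level`, default 255) inside a dark annulus (`myelin_level`,
default 30) on a bright background (`background_level`, default 245). The
defaults are the study conditions used throughout the tests: 120 axons over
32 slices at 0.8 µm section spacing and 2.6 px/µm in-plane resolution, with
inner diameters drawn from a clipped lognormal on [1.14, 6.04] µm — most
mass between roughly 1.3 and 2.3 µm, matching the caliber distribution of a
small cutaneous nerve branch.

Emulated features, each with a known ground-truth record:

* **Sinuous trajectories.** Axons are mobile along the nerve; each axon's
  centre follows independent per-axis sinusoids (`trajectory_amplitude`,
  default 1 µm per axis; `trajectory_wavelength`, nominally 30 µm, jittered
  ±30% per axon). Larger inter-slice intervals therefore move the next
  section's lumen farther from the previous seed, which is what drives the
  abortion rate up under z-subsampling.
* **Area fluctuation.** Per-slice lumen areas are multiplied by lognormal
  jitter with coefficient of variation `area_fluctuation_cv` (default 0.1);
  lognormal keeps areas positive and makes the normalized per-slice
  deviations directly comparable to the generator CV.
* **Open boundaries.** With probability `gap_probability` per axon per
  slice (default 0.05, chosen so that artifact-driven abortions occur at a
  few percent per axon-slice, the order observed in practice), an arc of
  `gap_arc` degrees (default 60) of the myelin ring is painted at
  background intensity. Because lumen and background intensities are
  deliberately close (255 vs 245), a gap lets region growing leak out of
  the axon — the dominant real-world failure mode. `gap_probability` may
  also be a function of normalized radial distance, to build phantoms whose
  artifact rate varies with position in the nerve.
* **Noise and misalignment.** Additive Gaussian intensity noise
  (`noise_sd`, default 4 on the 8-bit scale) and optional per-slice rigid
  jitter (`misalignment_sd`, translation px and rotation degrees; slice 1
  is never jittered so recovered alignments are directly comparable to the
  logged truth).

Rendering is analytic (no resampling): circles stay circles under the
per-slice rigid transform, and gap arcs rotate with it. Pixel intensities
are antialiased by a 3×3 subpixel coverage average, emulating optical
blur; this matters for registration, where hard-edged rasterization leaves
a systematic per-slice bias that random-walks across a long stack. The
label image used for ground truth is *not* antialiased — each pixel is
assigned by a pixel-centre test — so ground-truth lumen areas are
recovered exactly by counting label pixels.

Placement is a deterministic golden-angle spiral in axon order: sizes are
i.i.d. across the order, so axon caliber is independent of the distance to
the nerve centre (an assumption the position-effect analysis relies on),
and a phantom with all stochastic parameters switched off is identical for
any seed. Exclusion radii include the trajectory amplitude, so rings never
collide on any slice; if the frame cannot hold the requested axons, the
generator fails with an explicit packing error rather than degrading.

What the phantom does **not** emulate: unmyelinated fibers, fascicle-level
structure, staining chemistry, non-circular lumen shapes, cutting
artifacts other than ring gaps, or spatially correlated noise. Passing
tests therefore demonstrate correctness of the algorithms under controlled
conditions, not segmentation performance on real histology.

## Segmentation

`wildfire_fill()` grows a 4-connected region from a seed pixel over all
pixels whose intensity differs from the *seed pixel's* intensity by at most
`brightness_tol` (default 20 of 255). The predicate is fixed to the
original seed rather than a running mean — the simplest reading of
"stop if brightness differs by 20" — and 4-connectivity prevents leakage
through single-pixel diagonal gaps. Hue and saturation tolerances exist in
the configuration for completeness but are inert on 8-bit grayscale, which
is the intended working format. The region grower is implemented in C++
(it is the inner loop of the whole pipeline) and is property-tested for
exact equivalence against an independent synchronous-dilation fill written
in R.

`region_to_contour()` extracts the outer boundary as the 0.5-level
marching-squares iso-contour of the region mask. This "crack" contour
preserves the pixel-counted area, whereas a polygon through boundary-pixel
centres systematically loses about half a perimeter of area (the tests pin
the crack contour of a radius-20 px digital disk to within 2% of the
analytic disk). The contour is then smoothed by a circular moving average of
length `smooth_window` (default 7 vertices); if smoothing would make a
very thin polygon self-intersect, the unsmoothed boundary is kept.

`propagate_trace()` walks the stack slice by slice. The next seed is the
centroid of the previous accepted region; if that pixel is dark on the new
slice, the previous-region pixel nearest the centroid that is still within
tolerance is used; if none is, the trace aborts with reason `no_seed`. A
grown region is accepted iff its pixel area changed by less than
`area_change_stop` (default 0.99) relative to the previous accepted
region. The threshold is interpreted as
`|A_new - A_prev| / A_prev >= 0.99` — growth to roughly double (typically
a leak through an open boundary, reason `leak`, also flagged when the
region reaches the image border) or collapse to almost nothing (reason
`area_jump`). Regions below `min_region_px` abort with `too_small`.

On abortion the trace halts, mirroring the interactive tool waiting for an
operator decision. The `on_abort` hook emulates that operator: it may
supply a replacement seed on the same slice. The replacement region is
accepted unless it leaks again; in that case a manual circle congruent
with the previous accepted cross-section is inserted (`manual_circle()`,
which is also the documented fallback for axons too small to fill). Tying
the fallback radius to the previous accepted area keeps the area baseline
consistent, so one real artifact produces one abortion instead of
cascading down the remaining slices. Abortion *events* are what the QC
statistics count, whether or not tracing was resumed.

## Alignment

`align_rigid()` registers each slice to its already-aligned predecessor,
anchored at slice 1, with translation and rotation only. The estimate is
initialized by a coarse-to-fine rotation search maximizing the
phase-correlation peak (subpixel translation by parabolic interpolation of
the correlation surface) and refined by Nelder–Mead minimization of the
mean squared intensity difference over the interior 80% of the frame. Both
images are pre-smoothed with a σ = 1 px Gaussian during estimation:
bilinear resampling error is proportional to image curvature, and without
the pre-smoothing the sharp myelin edges leave a small but systematic
per-step bias. The final resampling of each slice is done once, from the
raw data, with the estimated transform.

The rigid resampler is written in the package (vectorized bilinear
inverse mapping) so that the rotation centre — the pixel-grid centre
`((H+1)/2, (W+1)/2)` — and the `(row, col)` axis conventions exactly match
the phantom's ground-truth transforms; recovered and injected transforms
are then directly comparable without coordinate gymnastics. On the default
120-axon stack, injected jitter of σ = 2 px / 1° is recovered to well
within 0.5 px and 0.25°. There is no quantitative alignment-acceptance
threshold inherited from practice (visual checks are customary); the drift
check against phantom ground truth takes that role here.

## Morphometry and statistics

Inner cross-sectional areas are shoelace polygon areas of the traced
contours in calibrated µm². The *idealized diameter* is the diameter of
the equal-area circle, `2 sqrt(A/π)`; it is used as a size label, not a
claim about lumen shape. For fluctuation analysis each axon's mean area is
set to 100% and per-slice deviations are expressed in percent
(`normalize_fluctuation()`), removing the quadratic size dependence before
classes are compared. Axons are grouped into `k` classes of identical size
by sorted diameter with a deterministic tie-break (`group_equal_n()`);
class comparisons use `kruskal.test()` across all classes and pairwise
Welch `t.test()`s (two-sided by default — the convention when only
significance thresholds are reported).

The abortion-versus-size relation is summarized two ways, because the
counts are strongly heteroscedastic: a Spearman rank correlation and a
one-phase exponential decay `y = plateau + A e^{-λd}` fitted with
`minpack.lm::nlsLM` (several λ starts, non-negative amplitude), reporting
λ and its length scale τ = 1/λ. The position analysis defines the nerve
centre per slice as the centroid of all axon centroids and each axon's
distance as the mean over slices; it first checks that size and distance
are uncorrelated (guarding against confounding) and then regresses
abortion counts on distance. Rates are reported to two significant
figures, matching how such rates are customarily printed; full precision
is available via `signif_digits = NULL`.

An optional g-ratio correction (`outer_diameter()`) converts inner to
outer fiber diameters, and the calibration carries an optional isotropic
shrinkage-compensation factor; neither has a package-supplied default
value beyond identity, since both are specimen-specific.

## Meshes

`loft_trace()` resamples every contour to a common vertex count (default
64) by angular parameterization about its centroid, using the same angular
origin on every ring so consecutive rings stitch without twist, then
connects consecutive rings with `2m` triangles per slab and closes both
ends with centroid fans. The result is watertight by construction and
oriented outward (checked by signed volume). Angular parameterization
assumes star-shaped contours — true for near-circular axon lumina, and the
known limitation for strongly concave shapes.

`hc_laplacian_smooth()` implements Laplacian smoothing with the "HC"
pushback: after moving each vertex to its neighbor average, the correction
vector relative to a blend of original and previous position is computed,
and a weighted average of own (β = 0.5) and neighboring corrections is
subtracted, cancelling most of the shrinkage of plain smoothing (α = 0,
β = 0.5 are the customary settings of the published scheme; the package
also exposes `laplacian_smooth()` for side-by-side comparison). Ten
iterations change an icosphere's volume by under 2% where plain Laplacian
smoothing loses over 15%.

`quadric_decimate()` is the standard quadric-error edge-collapse scheme:
per-vertex plane quadrics, optimal collapse position from the 3×3 system
(falling back to endpoints/midpoint near singularity), cheapest-edge-first
collapsing with a manifold link-condition check and a normal-flip
rejection test. Decimation stops at the target vertex fraction or earlier
if no admissible collapse remains, reporting the achieved fraction; Euler
characteristic and component count are preserved by construction.

Overlap errors between neighboring axons — vertices of one mesh strictly
inside another, which short-circuit downstream field simulations — are
counted by deterministic ray-parity containment along a fixed,
slightly irrational direction (avoiding edge-parallel degeneracies), with
bounding-box prefiltering per ordered pair. Vertex containment (rather
than face–face intersection) is the chosen definition because incorporated
*vertices* are the failure unit that matters downstream.

Export formats are ASCII PLY (single mesh; lists are merged) and VRML 2.0
with one `DEF <axon_id> Shape` per axon, so axon names survive the round
trip; the importer reads both formats back losslessly in topology and to
1e-6 µm in coordinates.

## Numerical choices and degenerate inputs

* Pixel coordinates are 1-based `(row, col)`; physical coordinates are
  pixel-centre µm (`(i - 0.5) · xy_scale`).
* Contours need ≥ 3 vertices and positive area; 1-pixel regions are
  `too_small`. Self-intersecting polygons are rejected by `polygon_area()`
  (O(n²) proper-crossing test) unless the caller vouches for them.
* The area-change test uses raw pixel counts, not smoothed polygon areas,
  so the abort decision is independent of contour smoothing.
* Blank (zero-variance) slices abort alignment with the slice index.
* `subsample_stack()` keeps slices `1, 1+s, 1+2s, …` and multiplies the
  calibrated z step by `s` (625 slices at step 2 → 313 slices at 1.6 µm).
* RNG is used only in the phantom generator and the statistical
  simulations; segmentation and meshing are fully deterministic, and axons
  are always processed in ascending `axon_id` order.

## Problem sizes used by the tests

The default test and acceptance runs use the 120-axon × 32-slice phantom
(320² px) for segmentation, QC statistics and alignment recovery; smaller
phantoms (15–30 axons, 2–12 slices) for module-level checks; 500 random
images up to 128² for the fill/oracle equivalence property; 1000 null
simulations (5 classes × 64 points) for the type-I calibration of the
class tests; and cylinders/icospheres of a few hundred vertices for the
mesh conservation laws. These sizes were chosen so the whole suite
exercises the full method chain at study-like scale while remaining
comfortable to run on a laptop.

## Known limitations

* Fully automatic multi-axon detection is out of scope: seeds come from
  the user (or the phantom's ground truth); the package automates
  propagation, QC and reconstruction, not initial axon discovery.
* The intensity predicate is seed-relative and global per slice; strong
  illumination gradients within one slice would need preprocessing.
* Angular contour parameterization distorts strongly non-star-shaped
  cross-sections.
* The VRML/PLY readers support the subset these writers emit, not the full
  specifications.
* Statistical analyses here quantify segmentation quality on phantoms;
  they make no claims about biological axon-caliber distributions.
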