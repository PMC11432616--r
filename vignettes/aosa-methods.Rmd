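---
title: "Mesh-based morphometry of the aorta and left heart: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based morphometry of the aorta and left heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aosa)
```

## What the package measures

Thoracic endovascular aortic repair (TEVAR) stiffens and reshapes the
aorta, and there is growing evidence that the heart remodels with it. Two
families of quantities capture that remodelling on segmented cardiac CT
angiography:

* **Aorto-septal angle (AoSA)** — the angle between the long axis of the
  left ventricle (apex to mitral-valve plane) and the axis of the aortic
  root (LVOT to sinotubular junction). It is obtuse in normal anatomy
  (roughly 100-130 degrees).
* **Ascending-aorta geometry** — centerline length, tortuosity index,
  equivalent diameter, the inclination of the first two centimetres
  relative to the aortic axis, and the lengths of the outer and inner
  curvature lines of the vessel wall.

The package takes triangulated surfaces (STL/PLY/OBJ/VTP) or NIfTI label
volumes of the aorta, left ventricle, and left atrium, plus a handful of
seed points, and computes all of the above deterministically. A statistics
layer turns repeated and paired measurements into coefficients of
variation, intraclass correlations, paired tests, and cohort summaries.

## The geometric model

### Heat-conduction field and isolines

The vessel wall is an open triangulated tube. We solve the Laplace
("steady heat conduction") equation on the surface with Dirichlet
conditions: the inlet boundary ring is held at a value of 1 and the outlet
ring at 0. The discretization is the intrinsic cotangent-weight
finite-element Laplacian, so the solution — and therefore every quantity
derived from it — converges under mesh refinement and is invariant to
rigid motion. On a cylinder the discrete solution reproduces the linear
closed form to solver precision, which the test suite asserts at 1e-6.

Isolines of the field at levels $k/(n+1)$, $k = n,\dots,1$ (default
$n = 100$) are closed curves sweeping the tube from inlet to outlet. They
are extracted by linear interpolation on mesh edges and chained across
faces; a vertex sitting exactly on a level is handled by perturbing the
level by 1e-12, which makes the edge-crossing tests deterministic. If one
level produces several closed components (possible across a bulge), the
longest is kept and a warning is raised. 100 levels give sub-millimetre
sampling on aortic segments of 60-100 mm; the count is a configuration
knob.

### Centerline

The raw centerline is the sequence of arc-length-weighted isoline
centroids, ordered by decreasing level and capped with the inlet/outlet
ring centroids. It is then smoothed over a 10 mm arc-length window and
resampled at 0.5 mm.

The smoother deserves a note. A plain centered moving average contracts
curved arcs towards their centre of curvature: for a window of half-width
$\delta$ on an arc of radius $R$ the radial bias is about
$\delta^2 / (6R^2)$, which is 0.26 % of length at $\delta = 5$ mm and
$R = 40$ mm. That sounds small, but the tortuosity index
$T = L/D - 1$ is itself small (0.07-0.21 in the cohort tables this
package ships), so a 0.26 % loss of $L$ becomes a 2-3 % relative error in
$T$. The default smoother is therefore a local quadratic regression in
arc length (Savitzky-Golay style): it removes centroid noise at the same
spatial scale but reproduces circular arcs without bias — phantom
tortuosity recovery improves by an order of magnitude. The classical
moving average remains available
(`compute_centerline(..., smooth_method = "moving_average")`) and keeps
its contraction property (smoothing never lengthens the polyline), which
the test suite checks in its own terms.

### Cross-sections, diameter, tortuosity

At every resampled point the surface is cut with the plane orthogonal to
the local tangent; among the closed intersection loops, the one that winds
around the centerline point is kept (this excludes far-wall intersections
in tight bends), and its planar polygon area $A$ gives the equivalent
circular diameter $D = 2\sqrt{A/\pi}$. Sections at the extreme ends of an
open tube may have no closed enclosing loop; they are reported `NA` and
excluded from segment means. For a segment of centerline length $L$ whose
endpoints are a straight-line distance $D_e$ apart, the tortuosity index
is $T = L/D_e - 1$ (the two uses of "D" in the field's notation are kept
apart in code as `mean_diameter` and `endpoint_distance_D`).

### Outer and inner curvature lines

Every isoline (plus the two boundary rings as first and last layers) is
resampled to 64 nodes equally spaced in arc length. Consecutive layers are
brought into angular correspondence: orientations are made consistent with
the sweep direction, and each layer's sampling phase is aligned to the
previous layer by minimizing summed squared distance — first over integer
cyclic shifts, then refined to a continuous fractional phase. The 64
corresponding chains are then wall "generator" paths; the longest is the
outer curvature line and the shortest the inner one, with ties broken
towards the smallest node index.

Two design points:

* A layered graph that connected *all* node pairs of consecutive layers
  would make the minimum path well behaved but the *maximum* path
  degenerate — with ~100 closely spaced layers the longest chain simply
  zigzags across the lumen and grows without geometric meaning. Restricting
  to angular correspondence makes both extremes well defined and, on
  planar-bend phantoms, reproduces the closed forms $(R \pm r)\,\theta$
  within a fraction of a percent.
* The fractional phase refinement matters: with integer-only alignment the
  residual (up to half a sample) varies from layer to layer wherever the
  meshing pattern changes, the "generator" wanders azimuthally, and path
  lengths inflate by several percent on mixed straight-plus-arc phantoms.

Path points are connected by straight chords between consecutive layers;
no geodesic refinement on the surface is attempted.

### Cardiac axes, AoSA, and inclination

The aortic axis runs from the centroid of the LVOT interface (the
separating surface between left ventricle and aorta) to the first
centerline point at the sinotubular junction. The ventricular axis runs
from the apex landmark to the centroid of the mitral interface (left
ventricle / left atrium). Interface patches come either from voxel-face
adjacency of the two labels (6-connectivity — the simplest watertight
definition of a separating surface) or are supplied directly; their
centroids are area-weighted triangle-centroid means.

The AoSA is the arccosine of the dot product of the two axis directions
after projection onto the measurement plane. In the original interactive
workflow that plane is picked by hand "parallel to the surface of the
heart"; that step is not reproducible from a description, so the default
here is the plane *spanned by the two axes* (normal = their cross
product), which makes the projection lossless: the reported angle equals
the direct 3D angle. An explicit `plane_normal` is accepted for strict
emulation of a chosen plane. Angles are reported in [0, 180] degrees
without supplementary folding, since the anatomical angle is obtuse.

If no apex landmark is given, the fallback picks the LV surface vertex
farthest from the mitral centroid — the elongated ventricle makes this a
stable choice — and the report flags that the fallback was used.

The ascending-aorta inclination (AAI) takes every resampled centerline
point with arc length $0 < s \le 20$ mm, forms the chord direction from
the centerline origin, and averages its angle to the aortic axis; the SD
over the window is reported alongside.

Repeatability is emulated by re-measuring the angle `n` times (default 5)
with the apex perturbed by seeded isotropic Gaussian jitter (default SD
2 mm); the coefficient of variation of those repeats is the repeatability
metric, and their mean is the reported angle. At 2 mm jitter the simulated
CV sits in the low-percent range, the same regime as trained observers
repeating the manual selection.

## From label volumes to surfaces

Surfaces are extracted from binarized labels as the 0.5 level set of the
indicator field using a marching-tetrahedra decomposition of the voxel
lattice (six tetrahedra per cube). The variant is table-free, produces a
consistent, watertight, manifold triangulation by construction, and leaves
the surface open exactly where the label touches the grid border. Vertices
are mapped to world millimetres through the NIfTI affine (RAS, 0-based
voxel indices).

Binary indicator fields give a faceted "staircase" surface whose raw area
overstates the smooth one by some 25-30 %. Extraction is therefore
followed by volume-preserving Taubin smoothing (lambda = 0.5,
mu = -0.53), with boundary rings held fixed. The default of 30
shrink/inflate pairs was chosen against the analytic sphere oracle: on a
radius-20 mm ball at 1 mm spacing it brings the area within ~3 % of
$4\pi r^2$ while changing enclosed volume by under 0.5 %. Ten iterations —
a common default for cube-based extraction — are not enough for the finer
tetrahedral faceting.

Mask-derived aortas are closed where the segmentation ends; the
`clip_surface()` operation cuts the mesh with a plane (exact edge
interpolation), opening the inlet at the sinotubular junction and the
outlet at the distal end of the analyzed segment. The clipping planes are
part of the run configuration.

## The statistics layer

* **Coefficient of variation**: 100 x sample SD / mean, with the n-1
  denominator — used throughout, since it reproduces every recomputable SD
  in the shipped tables.
* **ICC**: two-way random-effects, absolute agreement, computed from the
  subjects-by-raters mean squares, as ICC(2,1) for single ratings or
  ICC(2,k) for rater means, each with the standard F-based 95 % CI. Both
  forms are exposed because study reports sometimes name the mean-rating
  model while printing the single-measurement estimate; on the shipped
  inter-observer table the single form reproduces the published 0.96, and
  the fixture test pins that form. The point estimate is verified against
  an independent `aov()` variance-components oracle to 1e-9 on random
  layouts.
* **Paired comparisons**: two-sided paired t-tests on post - pre, with
  group means/SDs and percent change. No multiple-testing correction is
  applied — deliberately mirroring the small-cohort analysis style this
  reproduces; treat the p-values accordingly.
* **Percent change**: the default convention is
  $100\,(\text{post} - \text{pre})/\text{pre}$, which matches the signs of
  printed per-patient changes (increases positive). The opposite
  subtraction order, which some reports write as their formula while
  printing signs of the first convention, is available as
  `convention = "pre_minus_post"`.

The shipped fixture CSVs (`aosa_fixture()`) carry the printed per-patient
tables verbatim, including their small internal rounding inconsistencies
(e.g. an SD printed as 8.21 where the printed means give 8.2049, or a
group mean printed as 105.73 where its own column gives 105.71). Tests
compare recomputed aggregates to the printed values at the precision the
tables actually support.

## Synthetic phantoms and what they do (not) show

`make_tube()` sweeps a circle along a planar chain of straight segments
and circular arcs. Planarity is deliberate: it gives closed forms for
everything the pipeline measures — length $\sum \ell + \sum R\theta$,
tortuosity from the analytic endpoints, diameter $2r$, and curvature-line
extremes $L \pm r\,|\Theta|$ with $\Theta$ the total signed turn (for
same-sign bends this is the per-segment $(R \pm r)\theta$ rule). A helical
tube would have no such closed form for the extremal wall paths.

`make_heart()` builds a two-chamber model: an ellipsoidal left ventricle
(default semi-axes 25, 25, 45 mm — a normal-sized LV), a spherical left
atrium (radius 18 mm) abutting the base across the mitral plane at 60 % of
the long semi-axis, and an aorta tube (radius 12 mm) leaving the LVOT on
the equator, with a 30 mm aortic root between LVOT and sinotubular
junction so the aortic axis has anatomical length. The tube direction is
constructed at the requested angle to the LV long axis, so the true AoSA
is known exactly. The generator can also voxelize all three structures at
1 mm (the resolution class of cardiac CTA) to exercise the full
mask-to-mesh route, including interface extraction and plane clipping.

Default test-suite problem sizes — 1 mm mesh step, 100 isolines, 64
samples per contour, tube radii 8-15 mm, segment lengths 60-100 mm — were
chosen to match the dimensions and sampling density of adult thoracic
aortas in CTA while keeping any single phantom run in the low seconds;
they are the same defaults a user gets.

What the phantoms do *not* emulate: segmentation noise and partial-volume
effects, supra-aortic and iliac branches (the tube is branch-free by
contract; branch removal is the mask preparer's job), cardiac motion,
non-circular lumina of dissections, and wall thickness. Passing the
phantom suite therefore demonstrates correctness of the geometry engine,
not robustness to imperfect segmentations.

## Numerical choices and degenerate inputs

* Vertex merge tolerance on ingestion: 1e-6 mm; degenerate faces dropped.
* Meshes must be edge-manifold; violations are reported with the
  offending edges.
* Harmonic solve: sparse Cholesky on the interior block; residual norm
  checked against 1e-8.
* Isoline level ties: level perturbed by 1e-12 (deterministic).
* Extremal-path ties: smallest node index wins.
* `segment_metrics` rejects coincident endpoints (zero endpoint
  distance); `percent_change` and the CV reject zero means; the ICC
  requires a complete two-way layout with at least 2 subjects and 2
  raters.
* Degenerate axis projections (axis parallel to the measurement-plane
  normal) raise an error rather than returning a meaningless angle.

## Known limitations

* Curvature-line lengths on voxel-derived surfaces are biased upward by
  residual surface roughness (about 5 % on a 1 mm voxelized straight tube
  after default smoothing); swept meshes do not show this. More smoothing
  iterations or finer voxels reduce the bias.
* The discrete maximum principle can be violated by a few parts in 1e9 on
  meshes with very obtuse triangles; values are not clamped.
* The ascending-aorta distal boundary is not defined by the method itself;
  segment bounds are caller-supplied configuration.
* ICC confidence intervals at n = 10 subjects are wide and F-based; no
  small-sample correction is attempted.
* The statistics layer reproduces a five-patient analysis style: no
  multiplicity control, and single-patient "groups" report a mean with an
  `NA` SD rather than refusing.
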