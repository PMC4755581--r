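---
title: "Ray-fan segmentation and morphometry of vascular smooth muscle cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-fan segmentation and morphometry of vascular smooth muscle cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vsmcseg)
```

## The problem

Vascular smooth muscle cells (VSMCs) are long, thin, spindle-shaped cells
wound around the vessel wall. In two-channel confocal z-stacks of the
longitudinal-circumferential plane (F-actin marks the cell body, DAPI the
nucleus), cells form dense clumps: boundaries of touching and overlapping
cells merge, and classical single-cell segmentation (watershed, active
contours) fails because no isolated foreground blob corresponds to one
cell. `vsmcseg` reconstructs individual cells from such clumps and
measures their 3D geometry: length L, width W, thickness T, slenderness
L/W, the in-plane angle beta (circumferential direction = 0, range
[-90, 90)) and the out-of-plane tilt alpha (range [0, 90]).

## The edge blocking model

Segmentation is seeded at a nucleus. The nucleus centroid is the cell
center c0; thinning the nucleus mask yields a two-endpoint skeleton whose
long-axis endpoint defines the unit cell vector (n_x, n_y). Rays are
emitted from c0 at a uniform angular step. The scattering angle of a point
(x, y) is

    theta = [ atan2(n_y, n_x) - atan2(y - y0, x - x0) ]  (mod 2*pi),

expressed in degrees in [0, 360), so theta = 0 points along the cell
vector. Each ray carries an anisotropic emitting-length bound

    l(theta) = lc0 * (1 + lc1 * cos(theta)),   lc0 = 30, lc1 = 5  (pixels),

largest along the cell axis and decreasing away from it. As printed, this
form goes negative near theta = 180 degrees; because lc1 and lc0 are
described as the minimal and maximal emitting lengths, the implementation
clamps l into [lc1, lc0 * (1 + lc1)] (the literal form remains available
via `clamp = FALSE`). Because even the clamped bound cannot reach the
second tail, two consequences follow in this implementation:

* extended rays emitted from the skeleton endpoints (triggered where rays
  run within 15 degrees of parallel to the tail edges) use the axis
  alignment |cos theta| in the bound, so both tapering tails are covered;
* for gap detection an angle counts as covered when a boundary-class chain
  subtends it or a ray has an in-bound first intersection on one - gaps
  mark genuinely missing boundary coverage rather than bound shortfalls.

Every ray is intersected with every candidate edge chain. Intersections
are ranked by distance; a segment with at least one rank-1 intersection is
retained, segments hit only at rank 2 are blocked, and rank 3 and deeper
hits are discarded as noise. Runs of at least 3 consecutive uncovered rays
become gaps: Type I when both flanking retained segments are real (class
A) edges of the current cell, Type II otherwise (overlap or adhesion by
another cell).

## Edge preparation and classification

Each slice is smoothed with coherence-enhancing anisotropic diffusion
(5 iterations; diffusion strong along the local coherence direction, weak
across it, residual isotropic diffusivity 0.03), and edges are detected
with a Canny detector (Gaussian sigma 1.5 px, hysteresis thresholds at
0.1/0.2 of the gradient range). The edge map is thinned, spurs up to 3 px
are pruned, and bifurcation pixels - identified by the crossing number of
their neighborhood, not the raw neighbor count, so pixels merely adjacent
to a T-junction survive - are removed, leaving ordered single-pixel chains
with exactly two endpoints.

Chains are classified by the side criterion: class A when the mean
intensity gradient along the chain points toward the cell interior and the
second derivative just outside the chain is consistent with an outer
falloff; class B (false edge of another cell) when the gradient points
away; class C (touching edge) when the gradient is consistent but the far
side of the chain is also foreground. Inner edges - the rim of the dimmer
nucleus region inside the F-actin signal - are removed by region growing
over edge pixels seeded at the edge pixels inside the nucleus mask.
Class B chains take part in blocking (they occlude, and sectors occluded
by them are exactly the Type II gaps) but never contribute boundary
pieces.

## Gap filling

Type I gaps are bridged by bilateral spline interpolation: a cardinal
(Catmull-Rom family) spline with tension 0 is swept across the gap in both
directions, with the floating junction index on the receiving edge chosen
to minimize the accumulated curvature of the linked edge (and, as a second
variant, the length-normalized average curvature). Accumulated curvature
is the total absolute turning angle - a full circle accumulates 2*pi
regardless of sampling - and the average divides by the curve length, so a
circle of radius r averages 1/r. Of the four options (two directions, two
metrics) the final fill is the one whose intersection-point lengths
(distances of linked-edge points from c0, binned per ray) have the
smallest standard deviation; argmin ties resolve to the smallest index.

Type II gaps are first attempted by Laplace-verified PCA: the second
derivative of the intensity profile along each ray in the gap (rays
grouped within 7 degrees) still responds at the true boundary even where
the Canny detector failed; one-signed responses between the nucleus edge
and the first blocking hit are collected, and inside a sliding 5 x 5
window the first principal component of their covariance gives the local
edge direction, growing the edge piecewise from the window centroid. If no
qualifying points exist the caller falls back to spline interpolation.
All fills are cropped to the radius of the flanking retained edges plus
the stable-edge window, which stops ballooning extrapolations and growth
into the defocus halo.

Merged class C tail edges can be split by the auxiliary-line construction:
lines perpendicular to each cell's vector erected at the shared edge's
endpoints close a polygon, and the edge splits at its point of shortest
distance to the line joining the auxiliary ends.

Retained segments and fills are concatenated in clockwise ray order into
one closed loop. Self-crossing assemblies are repaired by dropping the
later-arriving crossing points, with a star-shaped (single-valued radius
per polar bin) rebuild as a last resort. Finally every boundary point is
refined to sub-pixel precision by moving it along the local outward normal
to the crossing of the local mid-intensity level; this removes the small
outward bias of gradient-maximum localization where the dimmer nucleus
sits just inside the trunk boundary.

## Stable edges across slices

An edge tracked from slice to slice should not move abruptly. For a
candidate point e_i and a seed edge E0 from a neighboring slice the
overlap score is

    O(e_i, E0) = 1 - min(d(e_i, e_0)) / w,    e_0 in E0,

with window width w = 5 px (O = 1 at distance 0, 0 at distance w,
negative beyond - left unclamped, which only affects averages, not the
per-ray maximum). Averaging O over M = 3 neighboring slices gives the
stability S; per ray line the maximal-O point is the stable-point
candidate, and an edge is stable when the fraction of its ray lines with a
positive-score stable point exceeds 30%. The ratio is over ray lines, not
chain points: a near-radial chain packs many points into few rays and
would otherwise never qualify. A median per-point displacement cap
(3 px/slice times M) enforces the no-abrupt-change rule while allowing
the genuinely new tail coverage each slice adds.

The per-cell sweep starts at the largest-area nucleus slice and proceeds
outward in both directions. Beyond the nucleus the ray origin follows the
boundary centroid, extrapolated by its slice-to-slice drift so the
cross-section strip of a tilted cell is tracked down the tails. Boundary
candidates are rejected when their area jumps by more than 60% over the
previous slice or their interior core brightness (90th percentile) falls
below 0.45 of the cell's reference - both symptoms of the defocus halo
past the axial caps masquerading as a cross-section. Two further guards
address clumps: slices of other cells are recognized by a capsule score
around each nucleus axis (half-width 1.5 x the nucleus minor half-width
plus 2 px, elongated 9:1) together with a tangent-alignment test
(fusiform edges run along their own cell's axis; a chain inside a
neighbor's capsule whose tangent follows the neighbor's axis by a
12-degree margin is cut out), and slices whose candidate chains are all
class B are skipped.

## Reconstruction and morphometry

Accepted boundaries are rasterized (even-odd scanline fill), stacked,
closed in-plane with a 3 x 3 structuring element and bridged across
single missing slices; a full 3D box closing is deliberately avoided
because it stretches the voxel columns of thin tilted cells. A three-slice
majority vote along z removes single-slice lateral jitter, and column ends
whose intensity falls below 0.42 of the column core are trimmed (the
in-plane boundaries cannot see the top/bottom surface inside their own
contour; 0.42 sits ~2.7 noise SDs below the mid-level so genuine cap
voxels survive). Surfaces are extracted by marching tetrahedra at the 0.5
iso-level of the (lightly smoothed) indicator and can be relaxed by
Laplacian smoothing; the voxel volume, not the mesh, is measured.

* L is the extent of the XY projection along the moment-fitted long axis.
* W is the median over 1-px axial bins (central 50% of L) of the per-bin
  pixel count - an area-based chord that is exact on rectangular fixtures,
  immune to single-pixel jitter, and robust to a localized bulge where a
  neighbor crossed.
* T is the 98th percentile (type-1 quantile, exact on uniform slabs) of
  per-column z extents, so one or two scatter-stretched columns cannot
  set it.
* beta is the signed angle between the projected long axis and the Y
  (circumferential) axis, folded into [-90, 90) with +/-90 mapping to
  -90; projections with axis ratio below 1.05 are flagged indeterminate.
* alpha is asin(|v_z|) of the first principal eigenvector of the 3 x 3
  covariance of the surface voxel coordinates (scaled by the voxel
  spacing). The "size-normalized" variant rescales each axis to unit
  variance (the correlation matrix) before the decomposition - the only
  reading of size normalization that can change the eigenvectors, since
  dividing all coordinates by a count leaves them untouched - and is
  provided for comparison; it is substantially less accurate and is not
  used for measurements. By default alpha is measured on the nucleus.

Cells whose reconstruction is internally inconsistent are not silently
measured but flagged for user-guided input, mirroring the semi-automatic
design: unstable slice coverage (more than a quarter of the spanned slices
missing, or fewer than 60% of the nucleus slices segmented), a width
inconsistent with the nucleus (W above the nucleus width plus 3 um), and
strongly asymmetric tails (|fore - aft| / (fore + aft) > 0.25 about the
nucleus center; the generator's spindles are symmetric and measurement
scatter on clean cells stays near 0.1, so a large asymmetry means one tail
was lost to occlusion).

The bimodal in-plane orientation population is summarized by a
two-component Gaussian mixture (unequal variances) fitted by
expectation-maximization via `mclust`, components sorted by mean.

## The virtual phantom

The tilt estimator is validated on ellipsoid meshes (UV sphere
triangulation, 64 azimuthal x 32 polar samples - fine enough that
triangulation error is far below the voxelization error) with semi-axes
(35, 10, 10) voxels for the 70-px long axis and (20, 6, 6) for the 40-px
one; the second size keeps the nucleus-like ~3.3 aspect ratio since only
the long axis is prescribed. The mesh is tilted out of plane, optionally
bent by rotating one end cap about X with interior vertices following a
harmonic (graph-Laplacian) interpolation of the displacement, and
voxelized slice by slice: the mesh cross-section polygon at each z plane
is filled by even-odd parity, yielding a solid object whose surface voxels
lie within half a voxel of the mesh. The sweep over tilts 10-60 degrees in
both sizes is the package's acceptance oracle for alpha; it also drives
`validateTilt()`.

## The synthetic stack generator

Real stacks are not deposited, so every downstream stage is exercised on
generated clumps. Cells are solid spindles: cross-section radii taper as
(1 - u^2)^0.6 along the axis, intensity is 1 in the core with a
smoothstep falloff over a 1 um band (gradient maximum exactly on the
boundary), nuclei are rendered as interior ellipsoids (15 x 3 x 3 um) in
the second channel and as a 35% intensity dip in the cell channel (the
origin of "inner edges"), intensity falls 15% from first to last slice,
and Gaussian read noise (SD 0.03) is added. Population parameters are the
VSMC study conditions: L ~ N(62.9, 14.9^2) um, W ~ N(4.6, 0.6^2),
T ~ N(6.2, 1.8^2), beta from the two-mode mixture (-19.4 +/- 9.3 and
10.9 +/- 4.7 degrees, equal weights), alpha half-normal with SD 7.6
degrees; voxels are 0.412 x 0.412 x 0.25 um. Crossing pairs place a
second cell 8-20 um away (bodies overlap, nuclei stay disjoint) with the
orientation drawn from the opposite mode. Geometry draws are repeated per
placement attempt so one oversized draw cannot jam the packing; placement
failure after 200 attempts reports infeasible packing.

What the generator does **not** model: the microscope point-spread
function (the smoothstep band is a crude stand-in), photobleaching,
refractive-index artifacts, curved or bent cells, and intensity texture
inside the cytoskeleton. Passing tests therefore demonstrate the
algorithmic chain on idealized spindles, not performance on real
micrographs.

## Problem sizes and determinism

Tests run the full pipeline on 200 x 200 x 60 single-cell stacks and
256 x 256 x 64 four-cell clumps (two stacks), and the phantom sweep at
its native resolution - sizes chosen so the whole suite completes in
minutes while every stage still operates in its intended regime. All
stochastic steps flow from a single integer seed; identical seeds give
bit-identical stacks and reports.

## Known limitations

Deep same-plane crossings - two cells overlapping at similar depth with
centers closer than roughly a cell width - cannot always be resolved
automatically: the occluded sector has no edges at all, and interpolation
across it can absorb part of the neighbor or truncate a tail. These are
the cases the semi-automatic design routes to the user (the QC flags
above); fully automatic recovery of every parameter for such cells is out
of reach of the present model, which matches the original workflow's
reliance on user-selected key edges exactly there. Thickness is resolved
only to about one z-slice at the axial caps, and sub-voxel accuracy in W
depends on the mid-level refinement assumption that the boundary is a
symmetric intensity step.
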