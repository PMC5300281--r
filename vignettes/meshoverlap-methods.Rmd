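---
title: "Mesh-based regional comparison of 3D segmentations: methods and design"
author: "MeshOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based regional comparison of 3D segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MeshOverlap)
```

## The problem

Small brain structures such as the hippocampus are segmented on T1-weighted
MRI by hand and by automatic tools (e.g. FSL-FIRST, FreeSurfer). Comparing
two segmentations of the same structure from different scans of one session
("back-to-back" scans) measures the *reproducibility* of a segmentation
method; comparing methods region by region reveals systematic differences in
the anatomical definitions they implement. Doing this at the voxel level
requires resampling one label map into the other's voxel lattice, and for a
structure only a few voxels across the interpolation error can swamp the
effect of interest.

MeshOverlap instead converts each label map once, in its native scan space,
into a closed triangulated surface, moves the *surfaces* (not the images)
with the rigid registration matrices, and computes volumes and overlap on a
fine common lattice of points. The package provides the full chain:

1. **Surface extraction** from integer label volumes (marching cubes on the
   binary indicator).
2. **Point-in-surface counting** on a regular sub-millimetre grid, giving
   volumes and the Jaccard overlap index
   $\mathrm{Jacc}(A,B) = |A \cap B| / |A \cup B| \approx
   N(A \cap B)/N(A \cup B)$,
   where $N(V)$ is the number of grid points inside surface $V$.
3. **Regional analysis**: a template mask is split 35/45/20 along its long
   axis into anterior, middle and posterior regions, and overlap is
   constrained to a region through
   $\mathrm{Jacc}_{ROI} = N((A\cap B)\cap ROI) \,/\,
   N((A\cap ROI)\cup(B\cap ROI))$.
4. **Registration QC** by the full-circle method: transforms around a closed
   cycle of scans are multiplied, $RM = \prod T_{ij}$; for perfect
   registrations $RM = I$. The residual is summarized as
   $\mathrm{TranslationTotal} = \lVert t(RM) \rVert$,
   $\mathrm{RotationTotal} = \arccos\!\big(\tfrac{\mathrm{tr}\,R(RM) - 1}{2}\big)$,
   and $\mathrm{Consistency} = \mathrm{Jacc}(S, RM(S))$ for a reference
   surface $S$; $1-\mathrm{Consistency}$ is the registration error.
5. **Statistics**: volumes $V$ and transformed overlap indices
   $J = \mathrm{Jacc}^9$ are modelled with Gaussian linear mixed models with
   factorial fixed effects (group, method, hemisphere, timepoint, region and
   selected interactions) and a per-subject random intercept; the fixed
   structure is chosen by backward AIC elimination.

Because real scan data cannot ship with a package, every stage is exercised
against synthetic phantoms with analytic ground truth: spheres and
ellipsoids (closed-form volumes), a bent tube (an elongated, curved,
asymmetric shape with a well-defined long axis), back-to-back pairs related
by a known rigid transform with optional boundary noise, and factorial
observation tables drawn from a known mixed model.

## Surface extraction

Label maps are binary in/out maps; the surface is the 0.5 iso-level of the
indicator sampled at voxel centres, so every surface/edge crossing sits at
an edge midpoint. The extraction is a marching-cubes variant organized
around *face contours*: on each face of each mixed cell a marching-squares
contour is built, directed so the positive region lies to its left seen
from outside the cell; the directed segments are chained into closed loops
on the cell boundary and fan-triangulated (a 3-loop becomes one triangle,
longer loops get a centroid vertex). Two properties motivate this
construction over the classic 256-case table:

* **Watertightness on binary data.** The ambiguous face case (two positive
  corners on a diagonal) is resolved by one fixed rule — positive corners
  are kept separate — applied identically by the two cells sharing the
  face, so adjacent cells always agree on the contour and the mesh can
  never crack. The classic table resolves ambiguity per *cell* and is known
  to produce holes exactly in these configurations, which binary data hit
  routinely.
* **Consistent orientation.** Loops inherit the boundary orientation of the
  positive patch, so triangle normals point out of the segmented region,
  nested components (cavities in noisy segmentations) subtract correctly
  from the enclosed volume, and the signed divergence-theorem volume
  ($\sum \det(v_1, v_2, v_3)/6$ over triangles) is positive.

Volumes are always zero-padded by one voxel layer before extraction so
labels touching the volume border still produce closed surfaces. Voxel
indices are 0-based and vertices are mapped to world millimetres through
the NIfTI affine exactly as stored; no axis reorientation is performed.

The iso-level (0.5) and interpolation (linear along edges) are package
choices — segmentation sources do not specify a surface convention — and
they are the symmetric, standard ones for indicator data. On a binary
sphere of radius 10 mm rasterized at 1 mm the extracted mesh encloses
4117 mm³ against the analytic 4189 mm³ (−1.7%); scikit-image's marching
cubes gives the same value on the same input, so this is the intrinsic
discretization bias of binarized data at that voxel size, not an artifact
of the variant. At 0.5 mm voxels the deficit falls to −0.5%. Convergence
and volume phantoms are therefore rasterized at 0.5 mm.

## Counting points inside surfaces

All volume and overlap numbers come from one estimator: the number of
points of a regular isotropic lattice inside a surface, times the lattice
cell volume. The lattice is built to enclose all compared surfaces with a
2 mm margin, at 0.5 mm spacing by default (0.25 mm for the tightest
phantom validations); all metrics of one comparison share one lattice,
since a ratio of counts is only meaningful on a common sampling domain.
The lattice origin is offset by an irrational fraction of the spacing
(spacing/π) below the bounding box so that lattice points never align with
the half-integer vertex lattice of voxel-derived meshes.

Insideness is decided by ray parity: a point is inside iff a ray cast along
+x crosses the surface an odd number of times, evaluated over all
components, so nested components form cavities. Three implementation rules
make this exact and fast:

* **Shared rays.** All lattice points of one $(y,z)$ column share one ray;
  crossings are computed once per column and parity is read off by binary
  search, which makes the cost per point negligible.
* **Exact tie-breaking.** A ray through a projected edge or vertex is
  resolved by a symbolic perturbation — the ray position is treated as
  $(y+\varepsilon, z+\varepsilon^2)$ for an infinitesimal
  $\varepsilon > 0$ — with the edge orientation determinant evaluated in a
  canonical vertex order so the two triangles sharing an edge see
  bit-identical values. Every degenerate configuration then resolves
  deterministically and the crossing count stays exactly consistent with a
  watertight mesh.
* **Pure prefiltering.** The acceleration structure (triangles binned by
  the columns their projected bounding boxes cover) only restricts which
  triangles are *tested*; it can never change a flag, and the test suite
  verifies bit-identical agreement with a brute-force all-triangle cast.

Points within $10^{-9}$ mm of a crossing are classified inside: the set is
measure-zero and a fixed rule keeps runs reproducible. (A point whose ray
is exactly tangent to the surface produces no crossing and falls back to
the parity rule.)

## Regions along the long axis

The long axis of a mask is the first principal component of the world
coordinates of its voxels — the standard operationalization of "the long
axis" for an elongated structure — with a deterministic sign convention
and a warning when the first two principal variances are too close for the
axis to be meaningful (ratio < 1.2). Cut planes perpendicular to the axis
are placed at *volume* quantiles so that the anterior/middle/posterior
fractions (default 35/45/20%) are met by construction; cuts land between
voxel projection values, so an axis-aligned synthetic shape — whose voxel
layers share projection values — can only meet the fractions to within
half a layer, while any obliquely oriented mask (i.e. any real anatomy)
meets them essentially exactly. Region meshes are built by masking voxels
*before* meshing, which keeps every region surface watertight and the
region occupancies an exact pointwise partition; the alternative (clipping
the whole-structure mesh with planes) produces open meshes the counting
engine cannot use. The one price is a one-voxel-scale sliver where the cut
walls meet the outer surface, because the whole-mask surface has no
interior walls there; at 0.5 mm voxels this keeps the sum of region
volumes within 0.1% of the whole-mask volume. A lattice point exactly on a
shared cut wall would be inside two region meshes; `regionOccupancy()`
resolves such ties with a fixed anterior > middle > posterior priority.

Anterior/posterior is anatomy, which a phantom does not have, so the
orientation of the axis is an explicit convention: `orientAxis()` flips
the axis (and swaps the labels) so it points along a user-supplied
anterior hint. Mapping a template region set into subject space applies a
general affine (two-stage affine registrations to standard space are
affine, not rigid); the transform matrices themselves are inputs in
world-mm FLIRT-style ASCII — registration is out of scope.

## Full-circle registration QC

`composeCircle()` multiplies the transforms of a closed cycle in the given
order and re-validates rigidity. "Trace" in the rotation-angle formula is
read as the trace of the 3×3 rotation block (the full 4×4 trace would
shift the argument by 1 and break the identity at the ends of the range),
and the arccos argument is clamped to $[-1, 1]$ against floating-point
drift in near-identity products. Note the arccos is ill-conditioned near
the identity: even a bit-exact identity product can report a rotation of
order $10^{-6}$ degrees, so "zero" rotation should be asserted on the
matrix, not the angle. The consistency index inherits a geometric
blind spot documented in `consistency()`: a rotationally symmetric
reference surface cannot see rotations about its own axis, which is why
the QC phantom of choice is the bent tube, not a sphere. The four standard
circles of a two-timepoint back-to-back session are provided as a preset
(`sessionCircles()`); arbitrary chains are accepted.

## Mixed models and backward AIC elimination

Whole-structure and regional Jaccard indices are bounded and left-skewed;
raising them to the 9th power is the package's fixed variance-stabilizing
transform for Gaussian modelling (`transformResponse()`), strictly
monotone so method rankings are preserved. Models are fitted with
`lme4`/`lmerTest` by **maximum likelihood** — not REML, because the
selection compares models with different fixed-effect structures, and
REML likelihoods are not comparable across those. Treatment coding with
the alphabetically first level as reference is fixed package-wide so that
predicted-cell tables reconstruct by adding single fitted offsets (e.g. a
model with additive hemisphere and timepoint effects predicts every other
hemisphere/timepoint table as a constant shift of a base table).

Backward elimination starts from the full model (all five main effects
plus the physiologically motivated interactions), computes per-term
type-III F tests with Satterthwaite denominator degrees of freedom, drops
the least significant droppable term — a main effect becomes droppable
only once no retained interaction contains it; p-value ties break toward
the higher-order term, then alphabetically — refits, and keeps the drop if
the AIC did not increase, stopping at the first refused drop. When the
Satterthwaite computation fails (degenerate designs), likelihood-ratio
p-values are substituted and the trace records which method was used.
Records with missing responses (e.g. undefined regional overlap when a
structure never enters a region — reported as missing, never as 0) are
dropped listwise; mixed models tolerate the resulting imbalance.

A property worth knowing when reading selection results: accepting the
drop of a $k$-parameter noise term requires its deviance contribution to
stay below $2k$, which a $\chi^2_k$ variable violates with probability
0.02–0.16. Over the ~13 droppable terms of the full volume model, a pure
AIC backward pass therefore retains at least one noise term in roughly
half of null datasets and stops early when it does. This is the
documented, intended behaviour of AIC-driven elimination (AIC optimizes
prediction, not sparsity); analyses that need stricter control should gate
drops on the per-term p-values also recorded in the trace.

The synthetic observation tables used to validate this machinery emulate
the target study design: 20 subjects in each of four diagnostic groups,
three segmentation methods, two hemispheres, two timepoints, three
regions; a volume-like response around 1.2 cm³ with subject SD 0.1 cm³ and
residual SD 0.05 cm³; injected effects of at least three residual SDs.
They are draws from exactly the model the fitter assumes — Gaussian,
balanced, single random intercept — so passing recovery tests demonstrates
correctness of the machinery, not robustness to the skew, outliers,
missingness and variance heterogeneity of real segmentation data.

## Phantoms: what they emulate and what they do not

`rasterize()` labels a voxel iff its centre lies inside the analytic shape
— matching the binary label maps segmentation tools emit, with no partial
volume. `makePair()` emulates two same-session scans: the second volume is
the shape moved by a known small rigid transform and re-rasterized, with
boundary voxels (those with an opposite-valued 6-neighbour) flipped at a
stated rate to mimic outline variability of raters and algorithms;
salt-and-pepper noise away from the boundary is deliberately not modelled.
Phantom sizes mirror the hippocampus scale (radii 4–20 mm) and MRI-like
resolutions (0.5–1 mm voxels). Problem sizes in the validation suite —
counting grids up to ~1.2 million points at 0.25 mm, 50 simulation
replicates of the 2880-observation design for selection studies — were
chosen so the full suite validates every claim on a single CPU in minutes.
What the phantoms do not reproduce: true MRI intensities and bias fields,
scanner-dependent distortions, anatomically realistic shapes, or
registration errors beyond a rigid perturbation.

## Known limitations

* Binary marching cubes carries a systematic volume deficit of order
  $h^2$ (≈1.7% at 1 mm voxels for a 10 mm sphere); compare volumes across
  methods at one fixed resolution, not across resolutions.
* The grid estimator's lattice granularity limits half-space volume
  splits to about half a lattice plane of the structure's cross-section.
* `consistency()` is blind to symmetry-preserving residuals (exactly
  rotationally symmetric surfaces only).
* AIC backward elimination over-retains noise terms at the documented
  rate; the selection trace carries the p-values needed for stricter
  post-hoc pruning.
* FLIRT matrices are consumed as world-mm transforms; FSL's internal
  scaled-voxel convention is not reinterpreted, and matrices must be
  supplied accordingly.
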