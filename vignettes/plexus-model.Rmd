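---
title: "A planar finite-element model of the neonatal brachial plexus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A planar finite-element model of the neonatal brachial plexus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexusfem)
```

## Why this model exists

Neonatal brachial plexus palsy is a stretch injury of the C5–T1 nerve complex
during birth. Cadaveric study of the injury mechanism in infants is largely
impossible, so a computational surrogate is used instead: a two-dimensional,
plane-stress elastic model of the spinal cord, the five nerve roots and the
three trunks, loaded by a tension representing depression of the shoulder
while the head stays aligned with the spine. The model answers comparative
questions — which root carries the highest stress, and how sensitive that
stress is to anatomical variation in the nerve-root angles — not absolute
injury predictions.

## Geometry and its reconstruction

All printed inputs are bundled: per-root cranial–caudal and transverse
diameters and the three segment lengths (`bp_root_dimensions()`), loading-rate
dependent material properties and loads (`bp_load_case()`), and total
cord-to-distal-trunk path lengths of 41.4 / 38.3 / 30.8 mm, which fix the
trunk lengths at 10.9 / 4.8 / 10.8 mm once the root path sums (30.5 … 13.5 mm)
are subtracted along the representative member root (C5 for the upper trunk,
C7 middle, C8 lower).

Several quantities a CAD sketch would need are *not* published, and are
reconstructed here as explicit, documented model constants:

* **Cord dimensions and attachment spacing.** A 7 mm wide, 30.2 mm long cord
  strip with attachment centres at y = 4.3, 8.8, 13.5, 19.6 and 26.2 mm
  (cranial → caudal). The wide C8–T1 gap is forced by arithmetic: C8 and T1
  must meet 20 mm and 13.5 mm from their attachments at faces ~2.6 mm apart,
  which is impossible unless the attachments are ≳ 6.5 mm apart.
* **Root angles** (`bp_default_angles()`: 73.85, 77.4, 50, 37.5, 49 degrees
  from the caudal cord direction). The source figure shows the angles but the
  text never prints them, so the bundled defaults were *calibrated*: path
  lengths hold for any angles (segment lengths are preserved exactly), and
  the angles were tuned until the baseline quasistatic junction-stress
  profile matched the published one (C5 0.246 MPa; C5/C6 highest). They are
  calibration artifacts, not measurements, and any study that depends on the
  absolute angles should treat them as such.
* **Middle-trunk kink** (31°, `bp_middle_trunk_kink()`): the middle trunk
  bends caudally toward the confluence of the plexus, its distal face kept
  perpendicular to the trunk axis. With a perfectly straight C7 + trunk
  column the C7 junction stress is pinned at ≈ 0.95× the applied pressure and
  cannot match the published 0.236 MPa; the kink is the geometric feature
  that diverts part of the pull transversely.

Trunks attach by construction: each two-root trunk's proximal face is the
straight segment through its member-root endpoints, split between members in
proportion to their widths. Under angle perturbation the face follows the
displaced endpoints, so trunks re-attach automatically and the in-plane trunk
width varies slightly with the angles. At the baseline the widths are 6.005 /
3.8 / 4.629 mm against the area-conservation nominal values 6.108 / 3.8 /
5.2 mm; exact nominal widths are geometrically incompatible with straight
roots of the printed lengths on a vertical cord (the root footprints on the
cord edge would overlap), so the nominal widths govern the load partition and
the member sub-face proportions while the drawn widths follow the closure.

```{r geometry}
geom <- build_plexus_geometry()
c(upper = path_length(geom, "upper"), middle = path_length(geom, "middle"),
  lower = path_length(geom, "lower"))
```

## Load partition

The applied tension is 5× the single-root rupture load, divided across trunks
by composite theory: equal modulus means force ∝ cross-sectional area, and
since the same elliptical areas (π/4 · d_cc · d_t, summed per trunk) convert
force back to pressure, one pressure serves all three trunks. The computed
values (0.3323 and 0.6523 MPa) agree with the published 0.332 and 0.653 MPa
within 0.2%; the published values are used as the applied loads when
reproducing the result tables, the computed ones act as a cross-check.

```{r loading}
load_partition("case1")
```

## Discretisation and solver

Each strip is meshed as a mapped grid of bilinear quadrilaterals with target
edge size 2 mm (minimum 0.2 mm — the sizes at which the reference model's
mesh convergence was reported); interface nodes are generated once and shared
bitwise, so meshes are conforming and bit-reproducible. The baseline mesh has
262 elements and 365 nodes, the same order as the reference model's 212
elements. Element quality is guarded by positive Jacobians at all Gauss
points and edge lengths within ±30% of the size bounds.

The solver assembles plane-stress stiffness from 2 × 2 Gauss quadrature by
default. Full integration was chosen over the reference software's reduced
one-point element because it needs no hourglass-control parameters and is
verifiable against textbook oracles; a `reduced_1pt` scheme with
stiffness-type hourglass stabilisation (coefficient 0.05) is available for
sensitivity checks and is expected to be slightly softer. Constant-strain
triangles are supported for wedge fills, although the bundled geometries mesh
all-quad. Boundary conditions:

* the cord midline column is fully clamped (encastré);
* the side edges of the five root strips carry *guided* supports: the
  displacement component transverse to the local nerve axis is fixed and the
  axial one left free, implemented exactly by rotating those nodes' degrees
  of freedom. This is the package's reading of the reference model's
  non-standard "XYSMM" condition "on the superior and inferior portions of
  the five nerves", which "allowed the nerve to stretch only in the plane of
  the model": guiding only the outer fan edges (mode `"outer"`) leaves the
  roots free to bend, drops the C5 stress to ~0.10 MPa and inverts the
  published C5/C6 > C8/T1 ordering, so `"all_nerves"` is the default and the
  alternatives remain selectable;
* the distal trunk faces carry the uniform pressure as consistent nodal
  loads along the outward face normal.

The linear system is solved by sparse Cholesky factorisation with prescribed
displacements eliminated exactly (no penalties), so the global equilibrium
residual is at machine precision (< 1e-8 required, ~1e-14 typical). Stresses
are recovered per element at the centroid (reported) and at the four Gauss
points (the per-element maximum is kept alongside); the von Mises scalar uses
the plane-stress form. The reported junction stress is the maximum element
value in the root's own region among elements touching the root–cord
interface — the stress *in the proximal nerve root*, mirroring how the
reference values are described; including adjacent cord elements is available
via `side = "both"`.

## Verification

Every solver property is tested against an independent oracle rather than
against the pipeline itself:

* element stiffness against a 4 × 4 Gauss brute-force integration;
* three rigid-body zero-energy modes per fully integrated element, five for
  the unstabilised reduced element, three again after stabilisation;
* uniform bar: exact uniaxial stress and end displacement pL/E to 1e-8
  relative, for ν = 0 and ν = 0.4;
* the classic distorted 5-element patch test, exact to 1e-10 for arbitrary
  seeded distortions (this oracle caught a real Jacobian transpose defect
  during development);
* Timoshenko cantilever tip deflection within 5%;
* linear scaling with the applied pressure, and invariance of stresses under
  rigid translation of the mesh;
* mesh convergence on the clamped-end bar with ν = 0.4 (a field outside the
  bilinear space): the stress window at the loaded end changes by < 2%
  between successive refinements at the model's mesh sizes.

## The variation study

`run_validation()` solves both loading cases on one mesh; the case-2 field
equals the case-1 field times the pressure ratio 1.967 exactly (linearity on
identical geometry — verified internally, and useful as a pipeline check).
`run_angle_sweep()` perturbs **all five root angles simultaneously** by each
delta in (−6°, −3°, 0°, +3°, +6°), rebuilds and remeshes the geometry at
fixed mesh parameters (re-meshing, not mesh morphing, mirrors how a CAD-based
model would be rebuilt and is a documented source of small discretisation
noise across variants), solves the chosen case, and reports per-root stresses
with integer-rounded percent changes against the delta-0 baseline. The
simultaneous reading follows the study description ("the angle between each
nerve root and the spinal cord (± three and six degrees)", one result column
per delta); a per-root `mode = "single"` is provided for exploration.
Infeasible perturbed geometries are recorded as failed cells and the sweep
continues.

## Synthetic fixtures: what passing tests do and do not show

The verification fixtures (`make_bar_fixture()`, `make_patch_fixture()`) carry
closed-form fields and establish that the discretisation and solver are
correct. `random_plexus()` jitters the baseline angles (default ±6°) and
optionally the segment lengths, resampling infeasible draws under a fixed
seed; 100 such geometries meshing and solving cleanly establishes pipeline
robustness over the anatomical neighbourhood of the baseline. None of this
validates the model *biologically*: the material is linear elastic while
nerve tissue is nonlinear and viscoelastic (the model consequently
under-predicts displacement and strain relative to experiments — a known
property of the linear assumption), the anatomy stops at the trunks, and
vertebral bodies and surrounding connective tissue are absent. Results are
meaningful as controlled comparisons (angle A vs angle B), not as absolute
injury thresholds.

## Numerical choices and problem sizes

* Units: mm, N, MPa throughout; unit plane-stress thickness, so edge
  pressures are line tractions numerically.
* Baseline runs use the 2 mm / 0.2 mm mesh (≈ 260 elements; one solve is a
  few hundred milliseconds), the convergence utility refines by factors 2 and
  4, and the property suite runs ~100 small solves — sizes chosen to keep the
  full suite around a minute while exercising every code path.
* Degenerate inputs fail loudly: overlapping root footprints name the
  offending pair, non-convex strips and non-positive Jacobians are rejected,
  under-constrained systems report remaining rigid-body modes, and
  conflicting fixed/guided constraints are errors.
* Determinism: node numbering is lexicographic per region, interface nodes
  are shared bitwise, and the sparse factorisation is ordered
  deterministically, so identical configurations give bit-identical outputs.

## Known limitations

The baseline angles, cord dimensions and middle-trunk kink are calibrated
reconstructions, so agreement of the baseline stress table with the published
one is partly by construction; the *mechanistic* content of the package lies
in the verified solver, the exact load partition, the linear-scaling and
ordering properties, and the sensitivity of the junction stresses to angle
perturbations. The junction stress sits at a re-entrant corner, which is
singular in the continuum limit; values are therefore tied to the reported
mesh sizes (as in the reference model) and the convergence statement is made
on the smooth bar fixture. Strains are path-averaged (displacement over
original length), not peak local strains.
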