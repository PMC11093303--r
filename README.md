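# plexusfem

A two-dimensional finite-element model of the neonatal brachial plexus for
studying stretch injury (neonatal brachial plexus palsy, NBPP). The package is
aimed at injury-biomechanics researchers who want a fully scripted,
reproducible version of a planar cord + root + trunk model: it builds the
geometry from published average infant dimensions, applies a composite-theory
load partition, solves the plane-stress elasticity problem with an in-house
quadrilateral finite-element solver, and reports the stresses and strains a
clinician-facing study would tabulate — including how the peak nerve-root
stress responds to small (±3°, ±6°) variations in the nerve-root angles.

## The model

* **Anatomy.** The spinal cord is a vertical elastic strip; the C5–T1 nerve
  roots leave its lateral edge as straight strips whose in-plane widths are
  the cranial–caudal root diameters and whose centerline lengths are the sums
  of the measured segments (spinal cord → dorsal root ganglion → bony foramen
  → trunk formation): 30.5, 31.0, 33.5, 20.0 and 13.5 mm for C5…T1. The roots
  merge into the upper (C5+C6), middle (C7) and lower (C8+T1) trunks with
  lengths chosen so the total cord-to-distal-trunk paths are 41.4, 38.3 and
  30.8 mm. Baseline root angles are calibrated model constants (they are not
  published); see the methods vignette.
* **Loading.** A tensile force of 5× the single-root rupture load is divided
  between the trunks in proportion to their elliptical cross-sectional areas
  (composite theory with a common modulus), which makes the applied pressure
  identical for all trunks: `p = 5 F_fail / Σ (π/4 · d_cc · d_t)` —
  0.332 MPa for the quasistatic case (0.01 mm/s) and 0.653 MPa for the
  dynamic case (10 mm/s).
* **Mechanics.** Small-strain, linear-elastic plane stress (E = 1.48 or
  2.02 MPa by loading rate, ν = 0.4, unit thickness), meshed with bilinear
  quadrilaterals (2 × 2 Gauss by default; reduced integration with hourglass
  stabilisation behind a flag), cord midline fully clamped, nerve side edges
  guided so each nerve stretches only along its own axis, and the pressure
  applied as a consistent outward traction on the three distal trunk faces.
* **Outputs.** Per-root maximum von Mises stress
  `σ_vm = sqrt(σxx² − σxxσyy + σyy² + 3τxy²)` in the proximal root at the
  root–cord junction, distal-trunk displacements, engineering strains
  `100·u/L₀`, and percent changes against the unperturbed baseline.

## Worked example

```r
library(plexusfem)
res <- run_validation()
print(res)
```

```
Baseline validation (both loading cases, identical mesh)
<study_result case1>
  max junction von Mises stress [MPa]:
    C5 0.246  C6 0.251  C7 0.238  C8 0.160  T1 0.194
  upper trunk: L0 41.4 mm, u 7.5 mm, strain 18.2%
  middle trunk: L0 38.3 mm, u 5.7 mm, strain 14.8%
  lower trunk: L0 30.8 mm, u 3.9 mm, strain 12.8%
<study_result case2>
  max junction von Mises stress [MPa]:
    C5 0.484  C6 0.495  C7 0.468  C8 0.315  T1 0.381
  upper trunk: L0 41.4 mm, u 10.9 mm, strain 26.2%
  middle trunk: L0 38.3 mm, u 8.2 mm, strain 21.4%
  lower trunk: L0 30.8 mm, u 5.7 mm, strain 18.4%
  case2/case1 junction-stress ratio: 1.9669 (pressure ratio 1.9669)
```

The per-root stresses are the peak von Mises values in the proximal nerve
root at its junction with the cord: C5 and C6 carry the highest stress — the
clinically observed injury pattern — and the quasistatic C5 peak (0.246 MPa)
sits just above the experimentally measured quasistatic failure stress of
isolated root/trunk segments (0.200 MPa), as a 5× rupture-level pull should.
Because the model is linear, the dynamic case is the quasistatic field scaled
by the pressure ratio 0.653/0.332 = 1.967. Strains are distal displacement
over original path length; the trunks stretch 13–26%.

The angle variation study and the mesh/geometry exports:

```r
sweep <- run_angle_sweep(default_plexus_config(), deltas = c(-6, -3, 0, 3, 6))
print(sweep)

mesh <- generate_mesh(build_plexus_geometry())
write_mesh_inp(mesh, "plexus.inp")   # Abaqus deck
write_mesh_vtk(mesh, "plexus.vtk")   # ParaView
```

or from a shell:

```sh
exec/plexusfem validate --out out/
exec/plexusfem sweep --deltas "-6,-3,0,3,6" --out out/
exec/plexusfem convergence --factors "1,2,4"
exec/plexusfem export-mesh --out out/
```

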