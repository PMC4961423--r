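---
title: "Methods: voxel finite-element impact analysis of the equine fetlock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel finite-element impact analysis of the equine fetlock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`fetlockfe` implements a subject-specific finite-element pipeline for the
distal condyle of the equine third metacarpal (MC3) articulating with the
proximal phalanx (P1) in the metacarpophalangeal (fetlock) joint, under two
load cases:

* **primary impact** — the 3 ms high-frequency transient when the hoof
  strikes the ground, modelled as an explicit dynamic solve of MC3 (every
  node moving distally at 3.55 m/s) against a stationary P1 with penalty
  contact and Coulomb friction;
* **midstance** — the low-frequency stance peak, modelled statically with
  surface pressures of about 19–20 MPa applied on the dorsal and palmar
  contact patches and the proximal end fully fixed.

Because no suitable micro-CT scans are available for distribution, the
pipeline is driven by a synthetic CT-like phantom whose density
architecture is controllable and whose geometry has closed-form properties
(volume, symmetry) that the test-suite exploits. Any density-valued raster
volume can be substituted for the phantom.

## Material mapping

Voxel values pass through the standard four-step chain:

1. HU to ash density, an affine scanner calibration
   (`ash = slope * HU + intercept`, clipped at zero);
2. ash to apparent density, a fixed ratio (default 0.6);
3. apparent density to elastic modulus by the equine-specific power law
   `E = 9040 * rho^2.35` (E in MPa, rho in g/cm^3, valid to the specimen
   ceiling of 2.47 g/cm^3);
4. element averaging: the modulus is evaluated **per voxel first** and then
   averaged over the voxels whose centres fall in each element.

Step 4's order is load-bearing: because the power law is convex, the mean
of moduli exceeds the modulus of the mean density for heterogeneous
elements, and the tests pin this down. The scanner calibration coefficients
are configuration, never hard-coded: the phantom writes HU through the same
calibration, so the chain is exercised end-to-end and round-trips exactly.
Poisson's ratio defaults to 0.3 everywhere, extending the value stated for
the dense augmentation elements to all bone.

Explicit impact models need the effective mass of the distal limb, not
just the modelled bone segment: a band of elements at the proximal cut end
(E = 16 GPa, nu = 0.3) is assigned the uniform density that brings the
total model mass to 5 kg. The density is solved from the mass deficit — a
nominal "500 g/cm^3" for such elements is a mass-tuning device, not a
material property, and on the default phantom the solved value lands near
600 g/cm^3.

## Phantom geometry

The phantom is constructive solid geometry chosen so that the solid is an
exact generalized cylinder: a shaft cylinder (radius 22 mm, length 60 mm)
capped by the height field `f = max(0, lobe_lat, lobe_med, ridge)`, where
the two condylar lobes are 14 mm spheres centred 7.5 mm either side of the
mid-plane and the sagittal-ridge sphere protrudes 2 mm above the inter-lobe
saddle. The analytic volume `pi r^2 L + integral(f)` (evaluated by a
high-resolution 2D quadrature that is independent of the voxelizer) is the
oracle for the voxel-count volume checks. The default dimensions are
life-size for an adult equine MC3 (condylar width about 43 mm):
the impact constants the phantom is solved under — the 5 kg effective
distal-limb mass and the 12 MPa/mm contact law — are defined for a joint of
this scale, and an undersized phantom would settle unphysically deep into
the contact and smear load onto the palmar condyle.

The cortical shell is realized as erosion layers on the voxel grid
(default 1.6 mm at 1.9 g/cm^3); the trabecular core is i.i.d. Gaussian
(0.85 +- 0.10 g/cm^3), clipped with everything else to [0, 2.47] g/cm^3.
One RNG stream per volume, seeded from the spec, gives bit-identical
volumes for identical inputs. The osteoarthritic variant raises density by
+0.5 g/cm^3 inside a 4 mm sphere centred ~4 mm beneath the palmar-medial
condylar surface — focal subchondral sclerosis at the site where it is
seen in advanced fetlock osteoarthritis. No quantitative sclerotic density
elevation is reported for such specimens, so the +0.5 g/cm^3 default
(roughly +40% over trabecular mean, within the range described for
sclerotic subchondral bone) is a package convention, documented rather than
calibrated. Surface erosion and pitting are not modelled.

The counterbody is the negative imprint of the condylar profile offset by
a 2 mm congruency gap, posed at the joint angle (default 165 degrees, the
extended end of the physiological 165–175 degree impact posture) by a
rotation about the mediolateral axis plus a distal lift that preserves the
gap on the dorsal side. The 165 degree default makes first contact
distinctly dorsal, which is what is observed at impact in this joint; the
gap default of 2.5 mm (one coarsened element plus margin) guarantees the
voxelized bodies start separated despite block quantization of both
surfaces and the spline's approximation of ledge corners.

## Meshing and regions

Meshing is voxel-based: one hex8 element per coarsened occupied block (at
least 50% of member voxels in the mask), with an optional tet4 mode that
splits each hex into six Kuhn tetrahedra with per-axis parity reflections
(conforming across neighbours). The default coarsening of 3 gives 2.4 mm
elements and ~7000 elements for MC3 — deliberately desk-scale; the
convergence harness quantifies what that costs in the same +-5% terms used
for full-scale models. Ten-node quadratic tetrahedra were not adopted:
voxel hex meshing is robust, assembles from a single congruent element
matrix, and keeps the explicit solver simple.

The up-facing distal boundary facets are partitioned into the eight
anatomical regions (dorsal/palmar x medial/lateral x condyle/parasagittal
groove) plus the sagittal-ridge band SR by mediolateral bands around the
mid-plane; band half-widths default to 0.25 and 0.60 of the lobe
separation, which is one admissible metric reading of the pictorial region
definitions. Ties at band edges go toward SR, and y = 0 counts as dorsal.
The two analysis slice planes sit +-5 mm from the transverse-ridge plane.

## Static solver

Small-strain isotropic elasticity; hex8 with full 2x2x2 Gauss integration
(no hourglass control needed), constant-strain tet4; element-centroid
stress recovery; sparse Cholesky factorization of the constrained system
(all model sizes in this package stay well below the ~150k-DOF point where
an iterative solver would be preferable). Equilibrium residuals are checked
to 1e-8. Verification: tip displacement `pL/E` and uniform von Mises on a
uniaxial bar, exact constant-stress patch tests, stress-free rigid-body
motion, six-dimensional rigid-body kernel of the free stiffness, and a
strain-energy match against an independent quadrature oracle.

## Explicit impact solver

Central-difference integration with lumped (row-sum) mass. The CFL-stable
step is `safety * min(L_char / c_dil)` (default safety 0.8, about 0.35 us
on the default model); the 0.25 ms interval quoted for such simulations is
physically impossible as an explicit step at these wave speeds and is
implemented as the **recording interval**, with the true step logged on the
history object.

Contact couples the MC3 articular surface nodes (slaves) to the P1
lower-surface facets through a linear pressure-overclosure law (12 MPa/mm)
with stick-slip Coulomb friction capped at `mu N` (mu = 0.007). With these
study constants the contact is deliberately soft: the contact half-period
is comparable to the 3 ms event, and the surfaces settle several
millimetres into one another before rebound. That regime shaped the
discretization:

* the master surface is reconstructed as a **plan lattice of facet
  heights** interpolated with a C1 quadratic B-spline (3x3 stencil), not
  matched facet-by-facet: on congruent voxel staircases a nearest-facet
  match flip-flops between ledges a full element apart and pumps energy
  at every crossing, and even a C0 (bilinear) surface leaves force jumps
  at cell lines that settling nodes chatter across, ratcheting energy in
  at a rate independent of the time step;
* all contact forces are the **exact gradient of the penalty potential**
  `U = 0.5 k A <z_s - z_surf(x_s, y_s)>^2`: the slave feels
  `k A d (dz/dx, dz/dy, -1)` and the contributing master facets receive
  the z reactions with the same spline weights. Interpolation stencils
  are clamped into the lattice and invalid cells inherit their nearest
  valid donor (ties broken toward the lower surface, which keeps mirror
  symmetry exact), so the potential is continuous and complete everywhere
  — a renormalized partial stencil at the lattice rim is not a gradient
  and visibly drifts. Voxel grids are sized in multiples of 12 so the
  coarsened block lattices of both bodies stay mirror-symmetric;
* surface patches steeper than 45 degrees carry no contact on either
  side: vertical projection is invalid there, their normals are mostly
  lateral, and on block-quantized voxel flanks they would fake
  interpenetration.

With this construction a frictionless 3 ms condyle-on-phalanx event
conserves total energy (kinetic + strain + contact) to machine precision,
and a mirror-symmetric phantom produces mirror-identical regional
pressures. Interpenetration beyond one element length produces a warning,
not an abort: with a linear soft-contact law and a 5 kg effective mass the
multi-millimetre settle is the intended operating point, and a hard limit
(`max_overclosure`) remains available. An energy-growth abort (total
energy exceeding ten times the initial kinetic energy) guards against
instability. Mass-proportional damping is off by default so the energy
audit is clean.

Verification: free flight before first contact is exact; a uniform
elastic rod striking a rigid plane reproduces the closed-form plateau
stress `v0 sqrt(E rho)` (20.08 MPa at E = 16 GPa, rho = 2000 kg/m^3,
v0 = 3.55 m/s) within 5%; contact force recomputes from the recorded
pressures; histories are bit-identical across runs.

## Regional analysis

A corner-anchored 8 x 20 grid of 160 equidistant points (spacings
`w/19` and `h/7` of the domain's bounding rectangle, so grids scale
affinely with condyle size) is superimposed on a mediolateral slice or on
the articular surface; the arrangement of the 160 points is a package
convention chosen to match the condylar aspect ratio, and is
configurable. Sampling is piecewise constant from element centroids,
consistent with per-element stress output. Points outside the bone
outline are projected to the nearest interior location and counted.

Impact stress fields entering regional tables are the **time-average of
each element's von Mises over the loaded phase** (frames with contact
force at least 25% of the event peak): an undamped explicit solve carries
high-frequency elastic ringing on top of the quasi-static contact
response, and single-frame sampling aliases it. Regional tables report
the arithmetic mean and maximum per region (or pooled by dorsal/palmar
location, the form in which headline comparisons are made); regions
without samples are absent, not zero.

The three harnesses mirror the full-scale study procedures:

* **convergence** — three mesh coarsenings (6, 4 and the default 3) of
  the same phantom under the same impact case; each coarser table's
  regional averages are compared with the finest at the +-5% criterion.
  At these desk-scale resolutions the moderate mesh does **not** generally
  meet +-5% — two to six elements across the condylar cap cannot resolve
  the subchondral gradient — and the report says so honestly; the harness
  demonstrates the procedure and the bookkeeping, which is what is
  testable without the original full-resolution scans.
* **sensitivity** — all moduli scaled by 1.5 (bone stiffening at impact
  strain rates); per-region ratios, true percent changes, and the
  per-point change distribution over the 160 samples. A stiffer model
  cannot lower the peak contact force, and the tests assert that
  direction only.
* **variant comparison** — healthy versus osteoarthritic phantom under
  identical protocols; signed absolute and percent differences. The tests
  assert directions only: impact stress in the lesion-adjacent region is
  not lower in the OA model, and midstance palmar stresses exceed impact
  palmar stresses (the impact contacts dorsally).

## What the phantom does and does not show

The phantom emulates the density architecture a CT-driven pipeline
consumes — cortical shell, noisy trabecular interior, focal sclerosis —
and the geometry of a bi-lobed condyle with a sagittal ridge. It does not
emulate trabecular microarchitecture or anisotropy, articular cartilage
(deliberately omitted from the impact models it mirrors), surface erosion,
or specimen-specific shape. Green tests therefore certify the pipeline's
mechanics — mapping, solvers, contact, analysis arithmetic, and the
qualitative contact/stress patterns — not the stress magnitudes of any
real specimen, which require the original scans.

## Numerical conventions

Internal units are mm / MPa / tonne / s (hence densities in tonne/mm^3 and
velocities in mm/s); the configuration surface accepts g/cm^3, m/s, ms and
kg and converts once at ingest. Coordinates: x lateral to medial, y palmar
to dorsal, z proximal to distal. Node and element indices are 1-based in R;
exporters translate (.inp 1-based, VTK 0-based). Voigt order is
(xx, yy, zz, xy, yz, zx) with engineering shear strains. Problem sizes
used throughout the tests and the acceptance script: ~7000 hex elements
for MC3 at coarsening 3 (about 33k DOF coupled with P1), chosen so a full
3 ms impact solves in about a minute.
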