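---
title: "Methods: subject-specific spine-segment FE models and their full-field validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subject-specific spine-segment FE models and their full-field validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spinefe` implements a complete modelling-and-validation workflow for
spine-segment finite-element (FE) models built from quantitative
computed tomography (QCT): density-calibrated material mapping, linear
elastic tetrahedral analysis under pot-driven rigid boundary
conditions, disc-stiffness calibration against a measured force, and a
quantitative comparison of predicted vertebral surface displacements
with full-field optical (DIC-style) measurements. This vignette
records the modelling choices, their assumptions, the tunable
parameters, and what the synthetic phantom does and does not
demonstrate.

## The model chain

### Density to elasticity

Voxel attenuation is converted to QCT-equivalent density with the
scanner calibration (defaults from a European Spine Phantom fit),

$$\rho_{QCT} = -0.016404 + 0.00085164 \cdot HU \;\; [\mathrm{g/cm^3}],$$

then to ash density $\rho_{ash} = 0.079 + 0.877\,\rho_{QCT}$, to
apparent density $\rho_{app} = \rho_{ash}/0.6$, and finally to an
elastic modulus by the vertebral trabecular power law
$E = 4730\,\rho_{app}^{1.56}$ MPa. Bone Poisson ratio is 0.3. All
constants are `material_law()` fields and can be replaced for a
different scanner or population.

Two numerical guards matter in practice. First, air and marrow voxels
produce non-physical densities; their modulus is floored at
`e_floor = 0.01` MPa so the stiffness matrix stays positive definite
while contributing negligible stiffness. Second, mapping onto elements
must decide whether to average density or modulus over the element:
`map_materials()` converts HU to modulus **per sample point** first and
then volume-averages the modulus, with 8 fixed symmetric interior
sample points per tetrahedron by default (`samples_per_element`
accepts 1, 4 or 8). The sampling uses trilinear interpolation on the
voxel-centre lattice, so the result is deterministic and independent
of element order. Because the alternative (averaging HU first) is also
defensible and the upstream tooling convention is not documented in
detail, the choice is exposed rather than buried: with the default the
homogeneous-field identity holds exactly (a constant grid maps the
same modulus to every element on any mesh), which is what the test
suite pins.

### The FE core

Meshes are 10-node isoparametric tetrahedra (tet10, VTK node
ordering); tet4 is supported for fast verification problems. Element
stiffness uses the 4-point degree-2 Gauss rule, exact for
straight-edged tet10 elements, assembled in compiled code into a
symmetric sparse operator. The linear solver is a sparse supernodal
Cholesky factorisation; the supernodal variant is forced explicitly
because the default heuristic can select the much slower simplicial
path on 3D elasticity patterns.

Boundary conditions replicate a pot-driven test: the base node set is
fully fixed, and the top node set is **rigidly tied** to a pilot node
SP placed at the pot marker-cluster centroid. Since the pilot motion
(R, T) is fully prescribed, each tied node has the known displacement
$u_i = R\,(x_i - SP) + T - (x_i - SP)$, with the rotation applied as a
full finite rotation matrix (a 5 degree rotation linearised would
already leave a second-order error of order $10^{-3}$ of the motion).
Rather than carrying Lagrange multipliers for what is a fully
determined constraint, the implementation eliminates the prescribed
degrees of freedom exactly and recovers reactions as the residual rows
of $K u$; the tied-node kinematic contract and global equilibrium
(reaction sum below $10^{-8}$ of the largest reaction) are asserted by
tests rather than by construction. The axial resultant is the
component of the base reaction along a configurable axial direction
(default +z, the cranio-caudal axis). Units are fixed: mm, N, MPa.

The embedding pots are not meshed: the tied surface is the vertebral
end surface itself, which is the natural reading of a rigid pot much
stiffer than the specimen.

### Rigid kinematics and registration

Pot motion is extracted from marker clusters by the closed-form SVD
(Kabsch) solution with the standard reflection guard, and reported
about an explicit reference point (the pilot); reporting rigid
transforms about the world origin is a classic source of
irreproducible translation components. Noise propagation follows the
expected $\sigma/\sqrt{M}$ law for M markers, which the test suite
verifies by simulation.

Measured surface clouds are aligned to the mesh by rigid registration:
a 2D Delaunay triangulation in the cloud's best-fit-plane
parameterisation provides the open triangulated surface (triangles
with edges beyond 3x the median point spacing are trimmed, removing
convex-hull bridging of concave outlines; clouds that fold over their
best-fit plane are rejected with a hint to split the region), and an
iterative-closest-point loop with nearest-surface-**node**
correspondences refines the pose from an initial transform. Two
deliberate deviations from common practice are worth recording:

* the default initialisation is the **identity**, not principal-axis
  alignment. Vertebral bodies (and the cylindrical phantom) are nearly
  axisymmetric, so inertia axes are ill-conditioned; scanner-frame
  data are already coarsely aligned, which is the regime the ICP
  contract (exact recovery of perturbations up to a few degrees and
  fractions of the point spacing) addresses. `init = "pca"` remains
  available for grossly misaligned clouds.
* correspondences use the nearest surface node rather than the nearest
  point on the triangulated surface, both inside the ICP loop and in
  the reported error statistics. At DIC resolution (about 2 mm, the
  same order as the mesh edge) the nearest-node statistic is the one
  the experimental registration-error definition uses, and it makes
  the recovery contract exactly testable. Mean distance, RMSE and
  maximum distance are all reported.

Registered displacement **vectors** are rotated only; they are free
vectors and must never be translated. This is asserted bit-exactly for
pure translations.

### Disc calibration

Disc mechanical properties cannot be derived from CT, so each disc is
a single homogeneous isotropic material with Poisson ratio 0.1 and one
shared unknown modulus. The modulus is calibrated so the predicted
axial reaction matches a measured force: since element stiffness is
linear in E, the bone and unit-disc operators are assembled once and
recombined per iteration, and the root of
$|F_{axial}(E)| - F_{target}$ is found by bisection with secant
acceleration inside a user bracket (default 0.1-100 MPa, the
physiologically plausible decade around reported disc moduli).
Iteration stops when the relative force mismatch is at most 0.1%, the
stop rule used experimentally; each iteration re-solves the full
system (no stiffness-update shortcut) and is logged to a tibble for
export. Endpoint monotonicity is checked before iterating, and targets
outside the attainable force range fail fast with both endpoint forces
in the message. Calibration-by-force-at-prescribed-motion is used
(rather than a stiffness-slope match): with a displacement-driven
rig the two coincide up to the force normalisation, and the 0.1%
axial-load criterion is stated in force terms.

### Validation metrics

Predicted and measured displacements are compared per RoI and per
component (RL, AP, SI mapped to x, y, z):

1. **Spherical averaging**: for each FE node of the RoI, the measured
   value is the unweighted mean of all cloud vectors within radius R
   of the node (R defaults to the registration RMSE; nodes with no
   cloud point in the sphere are dropped and counted).
2. **Cook's-distance screening**: for each component's regression, the
   points with Cook's distance above 4x the mean Cook's distance are
   removed, in a single pass, per component and per RoI. (Whether the
   original procedure pooled components is not documented; the
   per-component choice is recorded here and exposed via the config.)
3. **Ordinary least squares** of predicted on measured values gives
   R^2, slope and intercept; RMSE is the root-mean-square of
   (measured - predicted); %RMSE normalises by the maximum measured
   |component| in the RoI, which keeps it positive and
   scale-invariant; the mean percentage error excludes points with
   measured components below 1 um (the guard and the excluded count
   are reported) and the maximum absolute error completes the table.
4. **Error fields**: per-node absolute component errors and their
   Euclidean resultant (`diff_field()`), exportable as VTK point data
   for error maps.
5. **Bland-Altman agreement**: both the signed per-component flavour
   and the magnitude flavour (error resultant against the mean of
   measured and predicted magnitudes) are provided, since published
   agreement plots of this kind use either.

The SI sign flip seen in published regression plots is a plotting
convention; stored data keep the model-frame sign.

## The synthetic phantom

No experimental dataset ships with the package, so `make_phantom()`
generates a specimen with the statistical structure the pipeline
assumes: a stack of two full and two half cylindrical vertebral bodies
(25 / 12.5 mm high) separated by 9 mm disc layers, radius 20 mm (an
antero-posterior dimension of 40 mm, consistent with a 4 mm anterior
load offset being 10% of the disc AP dimension); a voxel grid at
0.24 x 0.24 x 1 mm with healthy background at 520 mg/cm^3 vBMD, an
ellipsoidal lytic lesion at 105 mg/cm^3 inside the upper full vertebra
(L2) and a uniformly osteoporotic lower full vertebra (L3) at
76 mg/cm^3, written in HU through the inverse calibration so the grid
is exactly consistent with the material chain; four non-coplanar flat
markers per pot; and DIC-like measurement noise (10 um constant
systematic offset plus 25 um per-component Gaussian random error).

The cross-section is meshed by a smooth square-to-disk mapping of a
structured grid, each cell split into six tetrahedra (a conforming
Kuhn subdivision). Two properties of this choice carry weight: there
are no degenerate cells at the axis (as polar meshing would produce),
and the meshed domain is the same cylinder at every refinement level,
so mesh-convergence statements measure discretisation error rather
than geometry changes.

### The over-determined loading triple

The experiment this workflow mirrors reports three numbers that cannot
simultaneously hold on an idealised geometry: a 60 N target load, a
measured pot motion with translations of several millimetres, and a
calibrated disc modulus of 1.92 MPa. On the real specimen they were
mutually consistent; on a solid-cylinder phantom the published motion at
1.92 MPa produces roughly 425 N. The phantom resolves this by treating
the **motion and the ground-truth modulus as its defining
conditions**: it applies the published motion unscaled, solves once, and
records the resulting axial force as its own "measured" force. The
disc-calibration self-consistency check then closes the loop exactly
(recovering 1.92 MPa to 0.1%), while the published 60 N remains the
default external calibration target (`phantom_spec()$target_load`) for
exercising the root finder against a measurement-style input. The
alternative - scaling the motion down to reach 60 N at 1.92 MPa - was
implemented and rejected: it shrinks the within-RoI displacement
spread to the order of the DIC noise, so regression quality would be
dominated by the noise floor rather than by anything the pipeline
does.

For the same reason the phantom cannot reproduce the physiological
surface-strain window (about -2500 to -3500 microstrain) quoted for
the real test at 60 N: a solid cylinder of healthy trabecular bone
under tens of newtons sits at tens of microstrain, and the real
window reflects thin-cortex geometry and stress concentrations absent
from an idealised phantom. `mean_axial_strain()` reports the phantom's
actual level (about -900 microstrain under the published motion), and
the tests assert the physically meaningful structure instead: anterior
compression, and larger compression anteriorly than posteriorly under
the flexion component.

### What passing tests do and do not show

The phantom exercises every contract of the pipeline - material
mapping against voxel-wise oracles, tied-node kinematics, registration
recovery of known mis-registrations, calibration parameter recovery,
and noise propagation into the regression metrics - under exactly the
noise model it injects (Gaussian, homoscedastic, uncorrelated, plus a
constant offset). Real DIC errors are spatially correlated, the real
surface is anatomical rather than cylindrical, real registration
confronts segmentation artefacts, and real discs are neither
homogeneous nor linear. Green tests therefore validate the
*implementation* of the workflow, not the biofidelity of any specific
model built with it.

## Problem sizes and numerical settings

The documented default mesh edge is 2 mm, matching the convergence
level chosen experimentally (roughly half a million degrees of freedom
for the full phantom). The test suite and the acceptance script run
the same phantom at 4-7 mm edges (tet10, roughly 15,000-65,000 degrees
of freedom), sizes chosen so the full suite solves dozens of systems
quickly on modest hardware while every contract stays
scale-independent; the
mesh-convergence check compares 6, 5 and 4 mm levels at fixed physical
probe points via quadratic FE interpolation. Other numerical defaults:
solver is a direct sparse Cholesky (supernodal) on the eliminated
system; calibration bracket 0.1-100 MPa with 0.1% force tolerance and
at most 50 iterations; ICP converges when the RMS change drops below
1e-6 mm within 100 iterations; triangulation edge cutoff 3x the median
nearest-neighbour spacing; spherical-averaging radius floored at a
quarter of the nominal DIC spacing when the registration RMSE is
numerically zero (noise-free closed loops).

## Known limitations

Linear small-strain elasticity is assumed throughout even though the
published pot motion compresses the phantom discs by tens of percent;
this matches the modelling convention of the workflow being mirrored
but is not a mechanical statement about real discs at that strain.
Posterior elements, ligaments and facet joints are absent by design.
The Cook's filter is single-pass and per component; re-iterated
filtering would remove more points and is deliberately not offered.
PLY import covers the ASCII variant only. The INP export is
write-only and covers nodes, elements, sets and the fixed-base
boundary block.
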