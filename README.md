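# spinefe

Subject-specific finite-element (FE) models of spine segments, built
from quantitative computed tomography (QCT) and validated against
full-field surface displacement measurements.

## Who this is for

Vertebral fragility fractures — from osteoporosis or lytic metastases —
motivate patient-specific FE models that estimate vertebral loading
directly from diagnostic CT. Before such models can support clinical
decisions their kinematic predictions must be validated against
experiments. `spinefe` implements the complete modelling-and-validation
workflow for a multi-vertebra lumbar segment loaded in
compression–flexion, for biomechanics researchers who want each stage
as an inspectable, testable function rather than a chain of commercial
tools:

1. **Material mapping** — voxel HU to QCT-equivalent density
   (ESP-style calibration), to ash and apparent density, to bone
   modulus:
   `ρ_QCT = −0.016404 + 0.00085164·HU`,
   `ρ_ash = 0.079 + 0.877·ρ_QCT`, `ρ_app = ρ_ash/0.6`,
   `E = 4730·ρ_app^1.56` MPa (ν = 0.3), volume-averaged per
   tetrahedral element.
2. **FE core** — tet4/tet10 small-strain linear elasticity (compiled
   assembly, sparse supernodal Cholesky), with the base fixed and the
   top surface rigidly tied to a pilot node SP at the pot
   marker-cluster centroid: `u_i = R(x_i − SP) + T − (x_i − SP)`.
3. **Rigid kinematics** — pot motion `(R_SP, T_SP)` extracted from
   marker trajectories by the Kabsch/SVD method with reflection guard.
4. **Registration** — DIC cloud triangulation (best-fit-plane
   Delaunay), point-to-surface-node ICP, and registration error
   statistics (mean, RMSE, max nearest-node distance).
5. **Disc calibration** — the one quantity CT cannot provide: a single
   homogeneous disc modulus (ν = 0.1) found by bisection with secant
   acceleration so the predicted axial reaction matches a measured
   force to 0.1 %.
6. **Validation metrics** — spherical averaging of measured vectors at
   radius R = registration RMSE, per-component Cook's-distance
   screening (4× mean cutoff), OLS of predicted on measured
   displacement (R², slope, intercept), RMSE, %RMSE (normalised by the
   max measured |component| per region), average/maximum error,
   pointwise error resultant `Diff = √(Error_x² + Error_y² +
   Error_z²)`, and Bland–Altman agreement.
7. **Phantom** — a synthetic two-vertebra-plus-disc specimen
   (cylindrical L1–L4 stack, lytic lesion at 105 mg/cm³, osteoporotic
   vertebra at 76 mg/cm³, DIC-like 10 µm systematic / 25 µm random
   noise) so the whole pipeline is testable without experimental data.

Everything tabular comes back as a tibble; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

The synthetic phantom at a 5 mm tet10 mesh (the documented default is
2 mm; coarser meshes keep the example fast — all contracts are
scale-independent):

```r
library(spinefe)

spec <- phantom_spec(edge = 5)      # geometry, densities, noise model
ph   <- make_phantom(spec)          # mesh + grid + BCs + ground truth
ph$mesh
#> <tet mesh> 11849 nodes, 7680 tet10 elements
#>   element sets: bone_L4, disc_3, bone_L3, disc_2, bone_L2, disc_1, bone_L1
#>   node sets: base, top, RoI_L2, RoI_L3

ph$achieved_force                   # the phantom's "measured" force (N)
#> [1] 425.06

# calibrate the disc modulus against that force
cal <- calibrate_disc_modulus(ph$mesh, ph$bcs)
c(cal$E_disc, 100 * cal$rel_diff)
#> [1] 1.9218 0.095                  # 1.92 MPa ground truth recovered
                                    # to < 0.1 %; force mismatch 0.095 %

# DIC-like measurement clouds, registered and compared
rois   <- c("RoI_L2", "RoI_L3")
clouds <- setNames(lapply(seq_along(rois), function(i)
  synth_dic_cloud(ph$solution, ph$mesh, rois[i], spec, seed = i)), rois)
register_rigid(clouds$RoI_L2, ph$mesh)
#> <registration> 2 ICP iterations
#>   mean distance 0.0000 mm, RMSE 0.0000 mm, max 0.0000 mm

val <- validate_displacements(ph$mesh, cal$solution, clouds,
                              as.list(rois), validation_config(radius = 0.5))
tidy(val)
#> # A tibble: 6 x 12
#>   roi    component r_squared slope intercept   rmse pct_rmse ...
#> 1 RoI_L2 RL            0.962 0.946   0.0496  0.0218    1.74
#> 2 RoI_L2 AP            0.997 0.991   0.0121  0.0239    0.811
#> 3 RoI_L2 SI            0.995 1.00   -0.00310 0.0244    0.550
#> 4 RoI_L3 RL            0.923 0.954   0.0117  0.0258    4.52
#> 5 RoI_L3 AP            0.989 0.992  -0.00515 0.0241    2.46
#> 6 RoI_L3 SI            0.989 0.971  -0.0689  0.0248    1.08
```

Reading the table: R² close to 1 and slope close to 1 mean the model
reproduces the spatial structure of the measured displacement field;
the RMSE of ~0.023–0.026 mm is exactly the injected 25 µm DIC noise
floor, i.e. at this noise level the model error is
measurement-limited. `autoplot(val)` draws the per-component
regression panels and `bland_altman()` the agreement analysis.

A thin command-line front end chains the same stages file-to-file:

```sh
Rscript inst/cli/spinefe.R phantom --edge 5 --out out/
Rscript inst/cli/spinefe.R pipeline --out out/
```

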