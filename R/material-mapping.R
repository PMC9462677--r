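#' Densitometric calibration and density-to-elasticity law
#'
#' The material chain used for vertebral bone:
#' \deqn{\rho_{QCT} = a_{cal} + b_{cal} \cdot HU}
#' \deqn{\rho_{ash} = a_{ash} + b_{ash} \cdot \rho_{QCT}}
#' \deqn{\rho_{app} = \rho_{ash} / r, \quad E = c \, \rho_{app}^{p}}
#' with defaults from a European Spine Phantom CT calibration
#' (`a_cal = -0.016404`, `b_cal = 0.00085164` g/cm^3 per HU), the
#' standard ash-density conversion (`a_ash = 0.079`, `b_ash = 0.877`),
#' ash-to-apparent ratio `r = 0.6`, and the vertebral trabecular
#' modulus power law `E = 4730 rho_app^1.56` MPa. Densities are g/cm^3,
#' moduli MPa. Moduli are floored at `e_floor` so that non-physical
#' voxels (air, marrow fat) cannot produce a singular stiffness.
#'
#' @param cal_intercept,cal_slope HU-to-QCT-density calibration (g/cm^3,
#'   g/cm^3 per HU); `cal_slope > 0`.
#' @param ash_intercept,ash_slope QCT-to-ash density conversion.
#' @param app_ratio ash/apparent density ratio, in (0, 1].
#' @param mod_coeff,mod_exp power-law coefficient (MPa) and exponent.
#' @param nu_bone bone Poisson ratio, in [0, 0.5).
#' @param e_floor minimum modulus (MPa) assigned to non-physical
#'   densities.
#' @return An object of class `spinefe_material_law`.
#' @export
material_law <- function(cal_intercept = -0.016404,
                         cal_slope = 0.00085164,
                         ash_intercept = 0.079, ash_slope = 0.877,
                         app_ratio = 0.6, mod_coeff = 4730,
                         mod_exp = 1.56, nu_bone = 0.3,
                         e_floor = 0.01) {
  if (cal_slope <= 0 || ash_slope <= 0)
    stop_input("calibration and ash slopes must be positive")
  if (app_ratio <= 0 || app_ratio > 1)
    stop_input("`app_ratio` must lie in (0, 1]")
  if (mod_coeff <= 0 || mod_exp <= 0 || e_floor <= 0)
    stop_input("`mod_coeff`, `mod_exp` and `e_floor` must be positive")
  if (nu_bone < 0 || nu_bone >= 0.5)
    stop_input("`nu_bone` must lie in [0, 0.5)")
  structure(list(cal_intercept = cal_intercept, cal_slope = cal_slope,
                 ash_intercept = ash_intercept, ash_slope = ash_slope,
                 app_ratio = app_ratio, mod_coeff = mod_coeff,
                 mod_exp = mod_exp, nu_bone = nu_bone,
                 e_floor = e_floor),
            class = "spinefe_material_law")
}

#' @export
print.spinefe_material_law <- function(x, ...) {
  cat("<material law>\n")
  cat(sprintf("  rho_QCT = %g + %g * HU   [g/cm^3]\n",
              x$cal_intercept, x$cal_slope))
  cat(sprintf("  rho_ash = %g + %g * rho_QCT;  rho_app = rho_ash / %g\n",
              x$ash_intercept, x$ash_slope, x$app_ratio))
  cat(sprintf("  E = %g * rho_app^%g MPa (floor %g MPa), nu = %g\n",
              x$mod_coeff, x$mod_exp, x$e_floor, x$nu_bone))
  invisible(x)
}

#' HU to QCT-equivalent density
#'
#' Applies the scanner/phantom calibration affine map element-wise.
#'
#' @param hu Hounsfield units, scalar or vector/array.
#' @param law a [material_law()].
#' @return QCT-equivalent density (g/cm^3), same shape as `hu`.
#' @export
hu_to_rho_qct <- function(hu, law = material_law()) {
  if (any(!is.finite(hu))) stop_input("`hu` must be finite")
  law$cal_intercept + law$cal_slope * hu
}

#' Invert the HU calibration (density to HU)
#'
#' Used by the synthetic phantom to write voxel grids in HU that map
#' back exactly onto prescribed vBMD values.
#' @inheritParams hu_to_rho_qct
#' @param rho_qct QCT-equivalent density (g/cm^3).
#' @export
rho_qct_to_hu <- function(rho_qct, law = material_law()) {
  (rho_qct - law$cal_intercept) / law$cal_slope
}

#' QCT density to ash density, apparent density and elastic modulus
#'
#' @param rho_qct QCT-equivalent density (g/cm^3), scalar or vector.
#' @param law a [material_law()].
#' @return A tibble with columns `rho_qct`, `rho_ash`, `rho_app`, `E`
#'   (MPa). Non-positive apparent densities are clamped to the modulus
#'   floor with a warning.
#' @export
rho_qct_to_modulus <- function(rho_qct, law = material_law()) {
  if (any(!is.finite(rho_qct))) stop_input("`rho_qct` must be finite")
  rho_ash <- law$ash_intercept + law$ash_slope * rho_qct
  rho_app <- rho_ash / law$app_ratio
  E <- rep(law$e_floor, length(rho_app))
  pos <- rho_app > 0
  if (any(!pos))
    rlang::warn(sprintf(
      "%d value(s) with non-positive apparent density; modulus clamped to the floor (%g MPa)",
      sum(!pos), law$e_floor))
  E[pos] <- pmax(law$e_floor, law$mod_coeff * rho_app[pos]^law$mod_exp)
  tibble::tibble(rho_qct = as.numeric(rho_qct),
                 rho_ash = as.numeric(rho_ash),
                 rho_app = as.numeric(rho_app), E = E)
}

#' Fused HU-to-modulus evaluation
#' @inheritParams hu_to_rho_qct
#' @return A tibble with columns `hu`, `rho_qct`, `rho_ash`, `rho_app`,
#'   `E`.
#' @export
hu_to_modulus <- function(hu, law = material_law()) {
  res <- rho_qct_to_modulus(hu_to_rho_qct(hu, law), law)
  dplyr::bind_cols(tibble::tibble(hu = as.numeric(hu)), res)
}

# fixed symmetric barycentric sampling lattices inside the reference tet
tet_sample_points <- function(n) {
  gauss4 <- rbind(c(0.5854101966249685, 0.1381966011250105,
                    0.1381966011250105, 0.1381966011250105))
  gauss4 <- rbind(gauss4,
                  gauss4[1, c(2, 1, 3, 4)],
                  gauss4[1, c(2, 3, 1, 4)],
                  gauss4[1, c(2, 3, 4, 1)])
  if (n == 1) return(matrix(0.25, 1, 4))
  if (n == 4) return(gauss4)
  if (n == 8) {
    # Gauss-4 plus the vertices shrunk halfway towards the centroid
    shrink <- 0.5 * diag(4) + 0.5 * matrix(0.25, 4, 4)
    return(rbind(gauss4, shrink))
  }
  stop_input("`samples_per_element` must be 1, 4 or 8")
}

#' Map voxel densities to per-element elastic constants
#'
#' For each bone element the modulus is evaluated voxel-wise (trilinear
#' interpolation of the grid at a fixed symmetric set of interior
#' sample points, HU converted to E per point) and then volume-averaged
#' over the element. Elements whose sample points all fall outside the
#' grid receive the floor modulus. Elements belonging to disc sets are
#' skipped: their material is set by the disc calibration.
#'
#' @param mesh a [tet_mesh()].
#' @param grid a [density_grid()].
#' @param law a [material_law()].
#' @param samples_per_element 1, 4 or 8 interior sample points (default
#'   8).
#' @return The mesh with `E` and `nu` filled for bone elements, plus a
#'   `material` tibble (element id, mean densities, modulus) stored in
#'   the mesh as attribute-free list entry `material`.
#' @export
map_materials <- function(mesh, grid, law = material_law(),
                          samples_per_element = 8) {
  stopifnot(inherits(mesh, "spinefe_tet_mesh"),
            inherits(grid, "spinefe_density_grid"))
  if (nrow(mesh$elements) == 0) stop_input("mesh has no elements")
  if (samples_per_element < 1)
    stop_input("`samples_per_element` must be >= 1")
  bary <- tet_sample_points(samples_per_element)
  bone <- which(!element_in_sets(mesh, disc_set_names(mesh)))
  if (length(bone) == 0) stop_input("mesh has no bone elements")
  corners <- mesh$elements[bone, 1:4, drop = FALSE]
  ns <- nrow(bary)
  ne <- length(corners[, 1])
  # sample coordinates: for each barycentric point, blend the corners
  vals <- matrix(NA_real_, ne, ns)
  for (s in seq_len(ns)) {
    pts <- bary[s, 1] * mesh$nodes[corners[, 1], , drop = FALSE] +
      bary[s, 2] * mesh$nodes[corners[, 2], , drop = FALSE] +
      bary[s, 3] * mesh$nodes[corners[, 3], , drop = FALSE] +
      bary[s, 4] * mesh$nodes[corners[, 4], , drop = FALSE]
    vals[, s] <- grid_sample(grid, pts)
  }
  rho_qct <- if (grid$value_kind == "HU") {
    law$cal_intercept + law$cal_slope * vals
  } else vals
  rho_ash <- law$ash_intercept + law$ash_slope * rho_qct
  rho_app <- rho_ash / law$app_ratio
  Epts <- ifelse(is.na(rho_app) | rho_app <= 0, NA_real_,
                 pmax(law$e_floor, law$mod_coeff * rho_app^law$mod_exp))
  # treat in-grid non-physical samples as floor, keep outside as NA
  Epts[!is.na(vals) & is.na(Epts)] <- law$e_floor
  Eel <- rowMeans(Epts, na.rm = TRUE)
  Eel[is.nan(Eel)] <- law$e_floor          # fully outside the grid
  mesh$E[bone] <- Eel
  mesh$nu[bone] <- law$nu_bone
  mesh$material <- tibble::tibble(
    element = bone,
    rho_qct = rowMeans(rho_qct, na.rm = TRUE),
    rho_ash = rowMeans(rho_ash, na.rm = TRUE),
    rho_app = rowMeans(rho_app, na.rm = TRUE),
    E = Eel)
  mesh$material$rho_qct[is.nan(mesh$material$rho_qct)] <- NA_real_
  mesh$material$rho_ash[is.nan(mesh$material$rho_ash)] <- NA_real_
  mesh$material$rho_app[is.nan(mesh$material$rho_app)] <- NA_real_
  mesh
}

#' Write the per-element material report
#'
#' @param mesh a mesh processed by [map_materials()].
#' @param path CSV output path.
#' @export
write_material_report <- function(mesh, path) {
  if (is.null(mesh$material))
    stop_input("mesh has no material report; run map_materials() first")
  readr::write_csv(mesh$material, path)
  invisible(path)
}
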