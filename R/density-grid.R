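#' Calibrated voxel density field
#'
#' A scalar field on a regular voxel lattice, the source of material
#' heterogeneity for the FE model. Values are stored at voxel centres;
#' `origin` is the centre of the first voxel. `value_kind` records
#' whether voxels hold raw attenuation (`"HU"`) or already-calibrated
#' QCT-equivalent density in g/cm^3 (`"rho_qct"`).
#'
#' @param values numeric array (`dims[1] x dims[2] x dims[3]`) or vector
#'   of length `prod(dims)` in x-fastest order.
#' @param origin,spacing length-3, mm. All spacing components must be
#'   positive.
#' @param dims length-3 integer voxel counts (only needed when `values`
#'   is a plain vector).
#' @param value_kind `"HU"` or `"rho_qct"`.
#' @return An object of class `spinefe_density_grid`.
#' @export
density_grid <- function(values, origin, spacing, dims = dim(values),
                         value_kind = c("HU", "rho_qct")) {
  value_kind <- match.arg(value_kind)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1))
    stop_input("`dims` must be three voxel counts >= 1")
  values <- as.numeric(values)
  if (length(values) != prod(dims))
    stop_input("`values` length does not match prod(dims)")
  if (any(!is.finite(values)))
    stop_input("grid values must be finite")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3 || length(spacing) != 3 || any(spacing <= 0))
    stop_input("`origin` and `spacing` must be length 3 with spacing > 0")
  structure(list(values = array(values, dims), origin = origin,
                 spacing = spacing, dims = dims, value_kind = value_kind),
            class = "spinefe_density_grid")
}

#' @export
print.spinefe_density_grid <- function(x, ...) {
  cat(sprintf("<density grid> %d x %d x %d voxels (%s), spacing %s mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$value_kind,
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample a density grid by trilinear interpolation
#'
#' Voxel centres define the interpolation lattice. Points outside the
#' lattice hull return `NA` (callers decide how to treat them, e.g. the
#' material mapper floors the modulus).
#'
#' @param grid a [density_grid()].
#' @param points n x 3 matrix of query coordinates (mm).
#' @return Numeric vector of interpolated values (`NA` outside).
#' @export
grid_sample <- function(grid, points) {
  points <- as_points3(points)
  n <- nrow(points)
  # continuous voxel index (0-based) of each point
  u <- sweep(sweep(points, 2, grid$origin), 2, grid$spacing, "/")
  out <- rep(NA_real_, n)
  d <- grid$dims
  inside <- u[, 1] >= 0 & u[, 1] <= d[1] - 1 &
    u[, 2] >= 0 & u[, 2] <= d[2] - 1 &
    u[, 3] >= 0 & u[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  u <- u[inside, , drop = FALSE]
  i0 <- pmin(floor(u), matrix(rep(d - 2, each = nrow(u)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- u - i0
  v <- grid$values
  idx <- function(dx, dy, dz) {
    # linear index into the array, 1-based
    (i0[, 1] + dx + 1) + (i0[, 2] + dy) * d[1] +
      (i0[, 3] + dz) * d[1] * d[2]
  }
  val <-
    v[idx(0, 0, 0)] * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    v[idx(1, 0, 0)] * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    v[idx(0, 1, 0)] * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    v[idx(1, 1, 0)] * f[, 1] * f[, 2] * (1 - f[, 3]) +
    v[idx(0, 0, 1)] * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    v[idx(1, 0, 1)] * f[, 1] * (1 - f[, 2]) * f[, 3] +
    v[idx(0, 1, 1)] * (1 - f[, 1]) * f[, 2] * f[, 3] +
    v[idx(1, 1, 1)] * f[, 1] * f[, 2] * f[, 3]
  out[inside] <- val
  out
}
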