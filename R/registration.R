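#' Surface displacement field (DIC-style point cloud)
#'
#' A point cloud in the reference (unloaded) configuration with one
#' displacement vector per point for a load frame, and a region-of-
#' interest label.
#'
#' @param points p x 3 matrix (mm).
#' @param displacements p x 3 matrix (mm).
#' @param roi label, e.g. `"RoI_L2"`.
#' @return An object of class `spinefe_surface_field`.
#' @export
surface_field <- function(points, displacements, roi = "custom") {
  points <- as_points3(points)
  displacements <- as_points3(displacements)
  if (nrow(points) != nrow(displacements))
    stop_input("points and displacements must have the same length")
  if (any(!is.finite(displacements)) || any(!is.finite(points)))
    stop_input("surface field coordinates and displacements must be finite")
  structure(list(points = points, displacements = displacements,
                 roi = roi),
            class = "spinefe_surface_field")
}

#' @export
print.spinefe_surface_field <- function(x, ...) {
  cat(sprintf("<surface field> %s: %d points, max |u| = %.4f mm\n",
              x$roi, nrow(x$points),
              max(sqrt(rowSums(x$displacements^2)))))
  invisible(x)
}

#' @export
as_tibble.spinefe_surface_field <- function(x, ...) {
  pts <- x$points
  u <- x$displacements
  tibble::tibble(point_id = seq_len(nrow(pts)), roi = x$roi,
                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

#' Triangulate a surface point cloud
#'
#' Computes a 2D Delaunay triangulation in the best-fit-plane
#' parameterisation of the cloud (principal-component projection) and
#' lifts it back to 3D, giving the open triangulated surface that rigid
#' registration tools require. Triangles with any edge longer than
#' `edge_cutoff` are removed, which trims the convex-hull bridging of
#' concave patch outlines.
#'
#' The cloud must be a height field over its best-fit plane (one
#' vertebral surface patch at a time); clouds that fold over are
#' rejected.
#'
#' @param points p x 3 matrix (mm), `p >= 3`.
#' @param edge_cutoff maximum triangle edge (mm); default 3x the median
#'   nearest-neighbour point spacing.
#' @param max_foldover tolerated fraction of triangles whose projected
#'   orientation is inverted (default 0.05).
#' @return list with `triangles` (t x 3 indices into `points`),
#'   `points`, `normals` (t x 3 unit normals, oriented away from the
#'   cloud centroid), `edge_cutoff`.
#' @export
triangulate_cloud <- function(points, edge_cutoff = NULL,
                              max_foldover = 0.05) {
  points <- as_points3(points)
  if (nrow(points) < 3) stop_input("need at least 3 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  pc <- svd(X, nu = 0)
  uv <- X %*% pc$v[, 1:2]                # in-plane coordinates
  if (is.null(edge_cutoff)) {
    nn <- RANN::nn2(points, points, k = 2)$nn.dists[, 2]
    edge_cutoff <- 3 * stats::median(nn)
  }
  # projectability: in a fold, sheets overlap in the projection, so a
  # point's nearest projected neighbour is a 3D-distant point
  if (nrow(points) > 3) {
    pair <- RANN::nn2(uv, uv, k = 2)$nn.idx[, 2]
    d3 <- sqrt(rowSums((points - points[pair, , drop = FALSE])^2))
    overlap <- mean(d3 > edge_cutoff)
    if (overlap > max_foldover)
      rlang::abort(sprintf(
        "cloud is not projectable onto its best-fit plane (%.1f%% of points overlap a distant sheet); split the region of interest",
        100 * overlap),
        class = "spinefe_geometry_error")
  }
  dd <- deldir::deldir(uv[, 1], uv[, 2])
  tri <- deldir::triMat(dd)
  e1 <- sqrt(rowSums((points[tri[, 1], ] - points[tri[, 2], ])^2))
  e2 <- sqrt(rowSums((points[tri[, 2], ] - points[tri[, 3], ])^2))
  e3 <- sqrt(rowSums((points[tri[, 1], ] - points[tri[, 3], ])^2))
  keep <- pmax(e1, e2, e3) <= edge_cutoff
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0)
    rlang::abort("no triangles survive the edge cutoff; the cloud is too sparse or anisotropic",
                 class = "spinefe_geometry_error")
  # fold-over check: orient every triangle counter-clockwise in the
  # plane parameterisation, then its lifted normal must point to the
  # same side of the best-fit plane
  a <- uv[tri[, 2], ] - uv[tri[, 1], ]
  b <- uv[tri[, 3], ] - uv[tri[, 1], ]
  cw <- (a[, 1] * b[, 2] - a[, 2] * b[, 1]) < 0
  tri[cw, c(2, 3)] <- tri[cw, c(3, 2)]
  u3f <- points[tri[, 2], , drop = FALSE] - points[tri[, 1], , drop = FALSE]
  v3f <- points[tri[, 3], , drop = FALSE] - points[tri[, 1], , drop = FALSE]
  n3 <- cbind(u3f[, 2] * v3f[, 3] - u3f[, 3] * v3f[, 2],
              u3f[, 3] * v3f[, 1] - u3f[, 1] * v3f[, 3],
              u3f[, 1] * v3f[, 2] - u3f[, 2] * v3f[, 1])
  n_plane <- crossp3(pc$v[, 1], pc$v[, 2])
  fold <- mean(n3 %*% n_plane < 0)
  if (fold > max_foldover)
    rlang::abort(sprintf(
      "cloud is not projectable onto its best-fit plane (%.1f%% folded triangles); split the region of interest",
      100 * fold),
      class = "spinefe_geometry_error")
  # 3D normals, oriented away from the cloud centroid
  u3 <- points[tri[, 2], , drop = FALSE] - points[tri[, 1], , drop = FALSE]
  v3 <- points[tri[, 3], , drop = FALSE] - points[tri[, 1], , drop = FALSE]
  nrm <- cbind(u3[, 2] * v3[, 3] - u3[, 3] * v3[, 2],
               u3[, 3] * v3[, 1] - u3[, 1] * v3[, 3],
               u3[, 1] * v3[, 2] - u3[, 2] * v3[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cen <- (points[tri[, 1], , drop = FALSE] +
            points[tri[, 2], , drop = FALSE] +
            points[tri[, 3], , drop = FALSE]) / 3
  flip <- rowSums(nrm * sweep(cen, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  list(triangles = tri, points = points, normals = nrm,
       edge_cutoff = edge_cutoff)
}

#' Rigid registration of a point cloud to the FE surface
#'
#' Iterative-closest-point refinement from an initial transform:
#' correspondences are nearest FE surface nodes (KD-tree), each
#' iteration solves the corresponded Kabsch problem in closed form, and
#' the loop stops when the RMS error improves by less than `tol` or
#' after `max_iter` iterations. Deterministic given inputs and `init`.
#'
#' Error statistics mirror the experimental definition: Euclidean
#' distance between each registered cloud point and the nearest node of
#' the model surface, summarised as mean, RMSE and maximum.
#'
#' @param moving p x 3 cloud (mm) or a [surface_field()].
#' @param fixed a [tet_mesh()] (its boundary surface nodes are used) or
#'   an m x 3 matrix of surface points.
#' @param init initial [rigid_transform()]; default identity. Use
#'   `init = "pca"` for inertia-axis pre-alignment of clouds far from
#'   the target (ambiguous for near-axisymmetric bodies).
#' @param max_iter,tol iteration cap and RMS-change convergence
#'   threshold (mm).
#' @return An object of class `spinefe_registration`: `transform` (the
#'   recovered moving-to-fixed transform), `distances` (per-point
#'   nearest-node distance after registration), `mean_distance`,
#'   `rmse`, `max_distance`, `iterations`, `trace` (per-iteration RMS).
#' @export
register_rigid <- function(moving, fixed, init = NULL, max_iter = 100,
                           tol = 1e-6) {
  pts <- if (inherits(moving, "spinefe_surface_field")) moving$points
         else as_points3(moving)
  fpts <- if (inherits(fixed, "spinefe_tet_mesh")) {
    surf <- mesh_surface(fixed)
    fixed$nodes[surf$nodes, , drop = FALSE]
  } else as_points3(fixed)
  if (is.null(init)) init <- rigid_transform()
  if (identical(init, "pca")) init <- pca_align(pts, fpts)
  about <- colMeans(pts)
  # re-express the initial transform about the cloud centroid
  trans <- rigid_transform(init$R,
                           transform_points(init, matrix(about, 1)) -
                             about, about = about)
  cur <- transform_points(trans, pts)
  trace <- numeric(0)
  last <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    nn <- RANN::nn2(fpts, cur, k = 1)
    rms <- sqrt(mean(nn$nn.dists^2))
    trace <- c(trace, rms)
    if (abs(last - rms) < tol) { converged <- TRUE; break }
    last <- rms
    target <- fpts[nn$nn.idx[, 1], , drop = FALSE]
    step <- extract_rigid_motion(cur, target, about = about)
    trans <- transform_compose(step, trans)
    cur <- transform_points(trans, pts)
  }
  if (!converged) {
    cnd <- rlang::error_cnd(class = "spinefe_convergence_error",
                            message = sprintf(
      "ICP did not converge in %d iterations (last RMS %.6g mm)",
      max_iter, utils::tail(trace, 1)))
    cnd$trace <- trace
    rlang::cnd_signal(cnd)
  }
  nn <- RANN::nn2(fpts, cur, k = 1)
  d <- as.vector(nn$nn.dists)
  structure(list(transform = trans, distances = d,
                 mean_distance = mean(d), rmse = sqrt(mean(d^2)),
                 max_distance = max(d), iterations = it,
                 trace = trace),
            class = "spinefe_registration")
}

#' @export
print.spinefe_registration <- function(x, ...) {
  cat(sprintf(
    "<registration> %d ICP iterations\n  mean distance %.4f mm, RMSE %.4f mm, max %.4f mm\n",
    x$iterations, x$mean_distance, x$rmse, x$max_distance))
  invisible(x)
}

#' @export
glance.spinefe_registration <- function(x, ...) {
  tibble::tibble(mean_distance = x$mean_distance, rmse = x$rmse,
                 max_distance = x$max_distance,
                 iterations = x$iterations)
}

# inertia-axis alignment: move cloud centroid onto target centroid and
# rotate principal axes onto principal axes, choosing among the four
# proper-rotation sign combinations the one with smallest nearest-
# neighbour RMS
pca_align <- function(pts, fpts) {
  cm <- colMeans(pts); cf <- colMeans(fpts)
  Vm <- svd(sweep(pts, 2, cm), nu = 0)$v
  Vf <- svd(sweep(fpts, 2, cf), nu = 0)$v
  best <- NULL; best_rms <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))       # keeps det = +1
    R <- Vf %*% S %*% t(Vm)
    if (det(R) < 0) next
    tr <- rigid_transform(R, cf - cm, about = cm)
    cur <- transform_points(tr, pts)
    rms <- sqrt(mean(RANN::nn2(fpts, cur, k = 1)$nn.dists^2))
    if (rms < best_rms) { best_rms <- rms; best <- tr }
  }
  best
}

crossp3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Apply a rigid transform to a surface field
#'
#' Points are mapped as `x -> R (x - about) + about + t`; displacement
#' vectors are rotated only (`u -> R u`), never translated.
#'
#' @param field a [surface_field()].
#' @param transform a [rigid_transform()].
#' @return The transformed field.
#' @export
apply_transform <- function(field, transform) {
  stopifnot(inherits(field, "spinefe_surface_field"))
  surface_field(transform_points(transform, field$points),
                transform_vectors(transform, field$displacements),
                roi = field$roi)
}
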