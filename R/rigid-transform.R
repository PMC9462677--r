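#' Rigid transform
#'
#' A proper rigid-body transform: rotation `R` (3x3, orthonormal,
#' `det(R) = +1`) plus translation `t` (mm), expressed about a reference
#' point `about` (mm). Points map as
#' `x -> R (x - about) + about + t`; free vectors (displacements) map as
#' `u -> R u` and are unaffected by `t` or `about`.
#'
#' Storing `about` explicitly removes the usual ambiguity of rigid
#' transforms reported about the world origin: the same physical motion
#' has different translation components depending on the reference
#' point. Experimentally extracted pot motions are naturally expressed
#' about the marker-cluster centroid (the pilot point).
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @param about length-3 reference point (mm); default the origin.
#' @param project if `TRUE`, snap `R` to the nearest proper rotation by
#'   SVD before validating. Useful for rotation matrices printed at
#'   limited precision.
#' @param tol orthonormality tolerance on `max|R'R - I|`.
#' @return An object of class `spinefe_rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0),
                            about = c(0, 0, 0), project = FALSE,
                            tol = 1e-6) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  about <- as.numeric(about)
  if (length(t) != 3 || length(about) != 3)
    stop_input("`t` and `about` must be length-3 numeric vectors")
  if (any(!is.finite(R)) || any(!is.finite(t)) || any(!is.finite(about)))
    stop_input("rigid transform components must be finite")
  if (project) R <- nearest_rotation(R)
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > tol || det(R) < 0)
    rlang::abort(
      sprintf("R is not a proper rotation (|R'R - I| = %.3g, det = %.6f); use project = TRUE for rounded matrices",
              err, det(R)),
      class = "spinefe_invalid_transform")
  structure(list(R = R, t = t, about = about),
            class = "spinefe_rigid_transform")
}

# closest matrix in SO(3) (Frobenius norm), with reflection guard
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' @export
print.spinefe_rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$R)
  cat(sprintf("<rigid transform>  rotation %.4f deg, |t| = %.4f mm\n",
              ang * 180 / pi, sqrt(sum(x$t^2))))
  cat("  t     =", sprintf("% .4f", x$t), "mm\n")
  cat("  about =", sprintf("% .4f", x$about), "mm\n")
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Apply a rigid transform to points or to free vectors
#'
#' @param transform a [rigid_transform()].
#' @param points,vectors numeric matrix (n x 3).
#' @return Transformed n x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  points <- as_points3(points)
  sweep(points, 2, transform$about) %*% t(transform$R) +
    matrix(transform$about + transform$t, nrow(points), 3, byrow = TRUE)
}

#' @rdname transform_points
#' @export
transform_vectors <- function(transform, vectors) {
  as_points3(vectors) %*% t(transform$R)
}

#' Invert or compose rigid transforms
#'
#' `transform_inverse(T)` undoes `T`; `transform_compose(a, b)` returns
#' the transform applying `b` first and then `a`. Both results are
#' expressed about the reference point of the first argument.
#'
#' @param transform,a,b rigid transforms.
#' @export
transform_inverse <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -Rt %*% transform$t, about = transform$about,
                  tol = 1e-6)
}

#' @rdname transform_inverse
#' @export
transform_compose <- function(a, b) {
  # a(b(x)) = RaRb (x - ca) + ca + tc with
  # tc = RaRb (ca - cb) + Ra (cb + tb - ca) + ta
  R <- a$R %*% b$R
  shift <- R %*% (a$about - b$about) +
    a$R %*% (b$about + b$t - a$about) + a$t
  rigid_transform(R, shift, about = a$about, tol = 1e-6)
}

#' Convert to/from a 4x4 homogeneous matrix (about the origin)
#' @param transform a rigid transform.
#' @export
transform_as_matrix <- function(transform) {
  H <- diag(4)
  H[1:3, 1:3] <- transform$R
  # about-the-origin translation of the same physical map
  H[1:3, 4] <- transform$about + transform$t -
    transform$R %*% transform$about
  H
}

#' @rdname transform_as_matrix
#' @param H a 4x4 homogeneous matrix.
#' @param about reference point for the stored transform.
#' @param tol orthonormality tolerance.
#' @export
transform_from_matrix <- function(H, about = c(0, 0, 0), tol = 1e-6) {
  stopifnot(all(dim(H) == c(4, 4)))
  R <- H[1:3, 1:3]
  t0 <- H[1:3, 4]
  # re-express about `about`: t = t0 - (about - R about)
  rigid_transform(R, t0 - about + R %*% about, about = about, tol = tol)
}

as_points3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop_input("expected an n x 3 matrix of coordinates")
  storage.mode(x) <- "double"
  x
}
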