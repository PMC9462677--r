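#' Extract rigid-body motion from corresponded point sets (Kabsch/SVD)
#'
#' Least-squares rotation and translation best aligning `ref` to `def`,
#' with the standard reflection guard (the smallest singular direction
#' is flipped when the raw SVD solution has negative determinant, so the
#' result is always a proper rotation). The translation is expressed
#' about the stated reference point, typically the marker-cluster
#' centroid (pilot point).
#'
#' @param ref,def m x 3 matrices of corresponded coordinates (mm),
#'   `m >= 3`, non-collinear.
#' @param about length-3 reference point; defaults to the centroid of
#'   `ref`.
#' @return A [rigid_transform()] with attributes `rms` (residual
#'   root-mean-square distance, mm) carried in field `rms`.
#' @export
extract_rigid_motion <- function(ref, def, about = NULL) {
  ref <- as_points3(ref); def <- as_points3(def)
  if (nrow(ref) != nrow(def))
    stop_input("`ref` and `def` must have the same number of points")
  if (nrow(ref) < 3)
    stop_input("at least 3 corresponded markers are required")
  cr <- colMeans(ref); cdf <- colMeans(def)
  A <- sweep(ref, 2, cr); B <- sweep(def, 2, cdf)
  ext <- svd(A)$d
  if (ext[2] < 1e-6)
    rlang::abort("marker cluster is (near-)collinear; rotation is not recoverable",
                 class = "spinefe_degenerate_geometry")
  H <- crossprod(A, B)                  # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  if (is.null(about)) about <- cr
  about <- as.numeric(about)
  # def ~ R (ref - about) + about + t
  t <- cdf - (R %*% (cr - about) + about)
  out <- rigid_transform(R, t, about = about, tol = 1e-9)
  fit <- transform_points(out, ref)
  out$rms <- sqrt(mean(rowSums((fit - def)^2)))
  out
}

#' Pilot point of a marker cluster
#'
#' Arithmetic mean of the reference marker coordinates; the point SP
#' through which pot displacements and rotations are prescribed.
#'
#' @param markers m x 3 matrix of reference marker coordinates (mm), or
#'   a marker tibble as returned by [read_markers_csv()] (frame 0 is
#'   used).
#' @return Length-3 point (mm).
#' @export
pilot_point <- function(markers) {
  if (is.data.frame(markers)) {
    f0 <- min(markers$frame)
    markers <- as.matrix(markers[markers$frame == f0, c("x", "y", "z")])
  }
  markers <- as_points3(markers)
  if (nrow(markers) == 0) stop_input("empty marker cluster")
  unname(colMeans(markers))
}

#' Marker trajectory CSV I/O
#'
#' Long format with columns `frame`, `marker_id`, `x`, `y`, `z` (mm);
#' the reference configuration is the lowest frame number (frame 0).
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_markers_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "marker_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    rlang::abort(sprintf("marker CSV must have columns %s",
                         paste(need, collapse = ", ")),
                 class = "spinefe_parse_error")
  df
}

#' @rdname read_markers_csv
#' @param markers marker tibble.
#' @export
write_markers_csv <- function(markers, path) {
  readr::write_csv(markers, path)
  invisible(path)
}

#' Rigid motion of a marker cluster between two frames
#'
#' Convenience wrapper: Kabsch extraction from the reference frame to a
#' chosen deformed frame, about the cluster centroid.
#'
#' @param markers marker tibble (see [read_markers_csv()]).
#' @param frame deformed frame number (default the largest).
#' @export
marker_motion <- function(markers, frame = NULL) {
  f0 <- min(markers$frame)
  if (is.null(frame)) frame <- max(markers$frame)
  ref <- markers[markers$frame == f0, ]
  def <- markers[markers$frame == frame, ]
  def <- def[match(ref$marker_id, def$marker_id), ]
  extract_rigid_motion(as.matrix(ref[, c("x", "y", "z")]),
                       as.matrix(def[, c("x", "y", "z")]))
}
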