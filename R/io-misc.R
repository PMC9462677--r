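#' Point-cloud CSV I/O
#'
#' Columns `point_id`, `x`, `y`, `z`, `ux`, `uy`, `uz` (mm) plus a
#' `roi` label and a `frame_tag` recording the coordinate frame the
#' cloud lives in (`"model"` after registration, `"dic"` before).
#'
#' @param field a [surface_field()].
#' @param path CSV path.
#' @param frame_tag coordinate-frame label stored with the cloud.
#' @export
write_cloud_csv <- function(field, path, frame_tag = "model") {
  df <- as_tibble(field)
  df$frame_tag <- frame_tag
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @return `read_cloud_csv()` returns the [surface_field()]; the frame
#'   tag is attached as attribute `frame_tag`.
#' @export
read_cloud_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("x", "y", "z", "ux", "uy", "uz")
  if (!all(need %in% names(df)))
    rlang::abort(sprintf("%s: cloud CSV needs columns %s", path,
                         paste(need, collapse = ", ")),
                 class = "spinefe_parse_error")
  num <- suppressWarnings(
    lapply(df[need], function(cl) as.numeric(cl)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    rlang::abort(sprintf("%s: non-numeric value in data row %d", path,
                         bad[1]),
                 class = "spinefe_parse_error")
  roi <- if ("roi" %in% names(df)) df$roi[1] else "custom"
  out <- surface_field(cbind(num$x, num$y, num$z),
                       cbind(num$ux, num$uy, num$uz), roi = roi)
  attr(out, "frame_tag") <-
    if ("frame_tag" %in% names(df)) df$frame_tag[1] else NA_character_
  out
}

#' ASCII PLY point-cloud I/O
#'
#' Vertex positions plus optional displacement vectors stored as the
#' scalar properties `ux`, `uy`, `uz`.
#'
#' @param field a [surface_field()] (or an n x 3 matrix of points).
#' @param path `.ply` path.
#' @export
write_cloud_ply <- function(field, path) {
  if (!inherits(field, "spinefe_surface_field"))
    field <- surface_field(field, matrix(0, nrow(as_points3(field)), 3))
  n <- nrow(field$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment spinefe cloud roi=%s", field$roi),
               sprintf("element vertex %d", n),
               "property double x", "property double y",
               "property double z", "property double ux",
               "property double uy", "property double uz",
               "end_header"), con)
  writeLines(apply(format(cbind(field$points, field$displacements),
                          digits = 17, trim = TRUE, scientific = TRUE),
                   1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_cloud_ply
#' @export
read_cloud_ply <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "ply")
    rlang::abort(sprintf("%s is not a PLY file", path),
                 class = "spinefe_parse_error")
  hend <- match("end_header", ln)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", ln, value = TRUE)[1]))
  roi <- sub(".*roi=", "", grep("roi=", ln[seq_len(hend)],
                                value = TRUE)[1])
  if (is.na(roi) || !nzchar(roi)) roi <- "custom"
  props <- sub("^property \\w+ ", "",
               grep("^property", ln[seq_len(hend)], value = TRUE))
  rows <- ln[hend + seq_len(nv)]
  vals <- suppressWarnings(
    t(vapply(strsplit(trimws(rows), "\\s+"),
             function(v) as.numeric(v), numeric(length(props)))))
  if (any(is.na(vals)))
    rlang::abort(sprintf("%s: non-numeric vertex row %d", path,
                         which(rowSums(is.na(vals)) > 0)[1]),
                 class = "spinefe_parse_error")
  colnames(vals) <- props
  disp <- if (all(c("ux", "uy", "uz") %in% props))
    vals[, c("ux", "uy", "uz"), drop = FALSE]
  else matrix(0, nv, 3)
  surface_field(vals[, c("x", "y", "z"), drop = FALSE], disp, roi = roi)
}

#' Rigid-transform JSON I/O
#'
#' Stored as a 4 x 4 homogeneous matrix (row-major, about the world
#' origin) plus the reference point, so the read-back transform equals
#' the original exactly.
#'
#' @param transform a [rigid_transform()].
#' @param path `.json` path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = transform_as_matrix(transform),
         about = transform$about),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  h <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(as.numeric(as.matrix(h$matrix)), 4, 4)
  transform_from_matrix(H, about = as.numeric(h$about), tol = 1e-6)
}

#' Abaqus INP export (subset)
#'
#' Writes nodes, C3D4/C3D10 elements, the element sets, node sets and
#' a `*BOUNDARY` block clamping the fixed set, for cross-checking the
#' model in external solvers. Export only.
#'
#' @param mesh a [tet_mesh()].
#' @param path `.inp` path.
#' @param fixed_set node-set name to clamp (default `"base"` when
#'   present).
#' @export
write_mesh_inp <- function(mesh, path, fixed_set = "base") {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("*HEADING", "spinefe export (mm, N, MPa)", "*NODE")
  wl(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  type <- if (mesh$order == 4L) "C3D4" else "C3D10"
  wl(sprintf("*ELEMENT, TYPE=%s", type))
  wl(apply(cbind(seq_len(nrow(mesh$elements)), mesh$elements), 1,
           paste, collapse = ", "))
  for (s in names(mesh$element_sets)) {
    wl(sprintf("*ELSET, ELSET=%s", s))
    wl(chunk_ids(mesh$element_sets[[s]]))
  }
  for (s in names(mesh$node_sets)) {
    wl(sprintf("*NSET, NSET=%s", s))
    wl(chunk_ids(mesh$node_sets[[s]]))
  }
  if (!is.null(fixed_set) && fixed_set %in% names(mesh$node_sets))
    wl("*BOUNDARY", sprintf("%s, 1, 3, 0.0", fixed_set))
  invisible(path)
}

chunk_ids <- function(ids, per_line = 12) {
  vapply(split(ids, ceiling(seq_along(ids) / per_line)),
         function(v) paste(v, collapse = ", "), character(1))
}
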