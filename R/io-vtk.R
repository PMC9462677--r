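#' VTK legacy ASCII mesh I/O
#'
#' Writes/reads a tet mesh as a legacy-format ASCII VTK unstructured
#' grid (cell types 10 = tet4, 24 = tet10, VTK node ordering). Element
#' and node sets, per-element elastic constants, and optional point
#' vectors (e.g. a displacement solution) and cell scalars travel as
#' named CELL_DATA / POINT_DATA FIELD arrays (`es_<set>` / `ns_<set>`
#' indicator arrays), so a write-then-read round trip restores the mesh
#' exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` file.
#' @param point_vectors optional named list of n x 3 matrices.
#' @param cell_scalars optional named list of per-element vectors.
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_vectors = NULL,
                           cell_scalars = NULL) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  npe <- mesh$order
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "spinefe tet mesh (mm)",
     "ASCII",
     "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", n))
  wl(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                  scientific = TRUE), 1, paste, collapse = " "))
  wl(sprintf("CELLS %d %d", ne, ne * (npe + 1)))
  wl(apply(cbind(npe, mesh$elements - 1L), 1, paste, collapse = " "))
  wl(sprintf("CELL_TYPES %d", ne))
  wl(as.character(rep(if (npe == 4L) 10L else 24L, ne)))
  cs <- c(list(E = mesh$E, nu = mesh$nu), cell_scalars)
  for (s in names(mesh$element_sets)) {
    ind <- numeric(ne); ind[mesh$element_sets[[s]]] <- 1
    cs[[paste0("es_", s)]] <- ind
  }
  wl(sprintf("CELL_DATA %d", ne),
     sprintf("FIELD celldata %d", length(cs)))
  for (nm in names(cs)) {
    wl(sprintf("%s 1 %d double", nm, ne))
    wl(format(as.numeric(cs[[nm]]), digits = 17, trim = TRUE,
              scientific = TRUE))
  }
  ps <- list()
  for (s in names(mesh$node_sets)) {
    ind <- numeric(n); ind[mesh$node_sets[[s]]] <- 1
    ps[[paste0("ns_", s)]] <- matrix(ind, ncol = 1)
  }
  for (nm in names(point_vectors)) {
    m <- as.matrix(point_vectors[[nm]])    # n x k, k = 1 or 3
    storage.mode(m) <- "double"
    ps[[nm]] <- m
  }
  if (length(ps)) {
    wl(sprintf("POINT_DATA %d", n),
       sprintf("FIELD pointdata %d", length(ps)))
    for (nm in names(ps)) {
      wl(sprintf("%s %d %d double", nm, ncol(ps[[nm]]), n))
      wl(apply(format(ps[[nm]], digits = 17, trim = TRUE,
                      scientific = TRUE), 1, paste, collapse = " "))
    }
  }
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @return `read_mesh_vtk()` returns the mesh; extra point vectors are
#'   attached as attribute `point_vectors`.
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- grep("^POINTS", ln)[1]
  if (is.na(i)) rlang::abort(sprintf("%s: no POINTS section", path),
                             class = "spinefe_parse_error")
  n <- as.integer(toks(ln[i])[2])
  pts <- scan_numbers(ln, i + 1, 3 * n, path, "POINTS")
  nodes <- matrix(pts$values, n, 3, byrow = TRUE)
  i <- grep("^CELLS", ln)[1]
  ne <- as.integer(toks(ln[i])[2])
  ntot <- as.integer(toks(ln[i])[3])
  cl <- scan_numbers(ln, i + 1, ntot, path, "CELLS")
  npe <- as.integer(cl$values[1])
  conn <- matrix(cl$values, ne, npe + 1, byrow = TRUE)
  if (!all(conn[, 1] == npe))
    rlang::abort(sprintf("%s: mixed cell sizes are not supported", path),
                 class = "spinefe_parse_error")
  elements <- conn[, -1, drop = FALSE] + 1L
  storage.mode(elements) <- "integer"
  read_field <- function(start) {
    out <- list()
    j <- start
    nf <- as.integer(toks(ln[j])[3])
    j <- j + 1
    for (f in seq_len(nf)) {
      h <- toks(ln[j])
      nc <- as.integer(h[2]); nr <- as.integer(h[3])
      vv <- scan_numbers(ln, j + 1, nc * nr, path, h[1])
      out[[h[1]]] <- matrix(vv$values, nr, nc, byrow = TRUE)
      j <- vv$next_line
    }
    out
  }
  cell_data <- list(); point_data <- list()
  ic <- grep("^CELL_DATA", ln)[1]
  if (!is.na(ic)) cell_data <- read_field(ic + 1)
  ip <- grep("^POINT_DATA", ln)[1]
  if (!is.na(ip)) point_data <- read_field(ip + 1)
  element_sets <- list(); node_sets <- list()
  for (nm in names(cell_data))
    if (startsWith(nm, "es_"))
      element_sets[[substring(nm, 4)]] <- which(cell_data[[nm]][, 1] > 0.5)
  for (nm in names(point_data))
    if (startsWith(nm, "ns_"))
      node_sets[[substring(nm, 4)]] <- which(point_data[[nm]][, 1] > 0.5)
  E <- if ("E" %in% names(cell_data)) cell_data$E[, 1] else NA_real_
  nu <- if ("nu" %in% names(cell_data)) cell_data$nu[, 1] else NA_real_
  mesh <- tet_mesh(nodes, elements, element_sets = element_sets,
                   node_sets = node_sets, E = E, nu = nu)
  extra <- point_data[!startsWith(names(point_data), "ns_")]
  if (length(extra)) attr(mesh, "point_vectors") <- extra
  mesh
}

# tokenise numbers starting at line `from` until `count` values are
# read; errors carry the offending line number
scan_numbers <- function(ln, from, count, path, what) {
  vals <- numeric(0)
  j <- from
  while (length(vals) < count) {
    if (j > length(ln))
      rlang::abort(sprintf("%s: truncated %s section", path, what),
                   class = "spinefe_parse_error")
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln[j]),
                                              "\\s+")[[1]]))
    if (length(v) && any(is.na(v)))
      rlang::abort(sprintf("%s: non-numeric value in %s at line %d",
                           path, what, j),
                   class = "spinefe_parse_error")
    vals <- c(vals, v)
    j <- j + 1
  }
  list(values = vals[seq_len(count)], next_line = j)
}

#' VTK legacy ASCII structured-points I/O for density grids
#'
#' The grid is stored as `STRUCTURED_POINTS` with the voxel values as
#' point scalars; the `value_kind` is recorded in the title line.
#'
#' @param grid a [density_grid()].
#' @param path `.vtk` file path.
#' @export
write_density_grid_vtk <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     sprintf("spinefe density grid value_kind=%s", grid$value_kind),
     "ASCII",
     "DATASET STRUCTURED_POINTS",
     sprintf("DIMENSIONS %d %d %d", grid$dims[1], grid$dims[2],
             grid$dims[3]),
     sprintf("ORIGIN %.17g %.17g %.17g", grid$origin[1], grid$origin[2],
             grid$origin[3]),
     sprintf("SPACING %.17g %.17g %.17g", grid$spacing[1],
             grid$spacing[2], grid$spacing[3]),
     sprintf("POINT_DATA %d", prod(grid$dims)),
     "SCALARS density double 1",
     "LOOKUP_TABLE default")
  wl(format(as.vector(grid$values), digits = 17, trim = TRUE,
            scientific = TRUE))
  invisible(path)
}

#' @rdname write_density_grid_vtk
#' @export
read_density_grid_vtk <- function(path) {
  ln <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  kind <- "HU"
  m <- regmatches(ln[2], regexpr("value_kind=\\w+", ln[2]))
  if (length(m)) kind <- sub("value_kind=", "", m)
  gd <- function(tag) {
    i <- grep(paste0("^", tag), ln)[1]
    if (is.na(i)) rlang::abort(sprintf("%s: missing %s", path, tag),
                               class = "spinefe_parse_error")
    as.numeric(toks(ln[i])[-1])
  }
  dims <- as.integer(gd("DIMENSIONS"))
  origin <- gd("ORIGIN"); spacing <- gd("SPACING")
  i <- grep("^LOOKUP_TABLE", ln)[1]
  v <- scan_numbers(ln, i + 1, prod(dims), path, "SCALARS")
  density_grid(v$values, origin = origin, spacing = spacing,
               dims = dims, value_kind = kind)
}

#' Raw-array + JSON header density-grid dialect
#'
#' Writes the voxel array as a whitespace-separated ASCII stream
#' (x-fastest order) beside a JSON header holding `origin`, `spacing`,
#' `dims`, `value_kind` and the data file name.
#'
#' @param grid a [density_grid()].
#' @param path path of the JSON header; the array is stored at
#'   `<path>.raw.txt`.
#' @export
write_density_grid_raw <- function(grid, path) {
  raw_path <- paste0(path, ".raw.txt")
  jsonlite::write_json(
    list(origin = grid$origin, spacing = grid$spacing,
         dims = grid$dims, value_kind = grid$value_kind,
         data_file = basename(raw_path), order = "x-fastest"),
    path, auto_unbox = TRUE, digits = NA)
  writeLines(format(as.vector(grid$values), digits = 17, trim = TRUE,
                    scientific = TRUE), raw_path)
  invisible(path)
}

#' @rdname write_density_grid_raw
#' @export
read_density_grid_raw <- function(path) {
  h <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- scan(file.path(dirname(path), h$data_file), quiet = TRUE)
  density_grid(vals, origin = h$origin, spacing = h$spacing,
               dims = h$dims, value_kind = h$value_kind)
}

#' Export mesh and solution as a VTK file with displacement vectors
#'
#' Point data hold the displacement field, cell data the axial strain
#' and modulus, ready for error-map style inspection in ParaView.
#'
#' @param mesh the solved mesh.
#' @param solution a [fe_solve()] result.
#' @param path `.vtk` output path.
#' @export
write_solution_vtk <- function(mesh, solution, path) {
  write_mesh_vtk(mesh, path,
                 point_vectors = list(displacement = solution$U),
                 cell_scalars = list(strain_zz = solution$strain[, 3]))
}
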