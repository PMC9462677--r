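#' Tetrahedral FE mesh
#'
#' Nodes (mm), tet4 or tet10 connectivity (VTK node ordering: corners
#' first, then edge midpoints (0,1), (1,2), (0,2), (0,3), (1,3), (2,3)),
#' named element sets (e.g. `bone_L2`, `disc_1`), named node sets (e.g.
#' `base`, `top`), and per-element elastic constants `E` (MPa) and `nu`.
#'
#' Validation enforces strictly positive element Jacobians (corner
#' tetra volume), that every node is referenced by at least one element,
#' and - for tet10 - that midside nodes sit at the edge midpoints within
#' 1e-9 mm.
#'
#' @param nodes n x 3 numeric matrix (mm).
#' @param elements e x 4 or e x 10 integer matrix of 1-based node ids.
#' @param element_sets named list of element index vectors.
#' @param node_sets named list of node index vectors.
#' @param E,nu per-element elastic constants (recycled if length 1; may
#'   be `NA` before material mapping).
#' @param validate check mesh invariants (default `TRUE`).
#' @return An object of class `spinefe_tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, element_sets = list(),
                     node_sets = list(), E = NA_real_, nu = NA_real_,
                     validate = TRUE) {
  nodes <- as_points3(nodes)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (!ncol(elements) %in% c(4L, 10L))
    stop_input("`elements` must have 4 (tet4) or 10 (tet10) columns")
  if (nrow(elements) == 0) stop_input("mesh has no elements")
  ne <- nrow(elements)
  E <- rep_len(as.numeric(E), ne)
  nu <- rep_len(as.numeric(nu), ne)
  mesh <- structure(
    list(nodes = nodes, elements = elements, order = ncol(elements),
         element_sets = element_sets, node_sets = node_sets,
         E = E, nu = nu, material = NULL),
    class = "spinefe_tet_mesh")
  if (validate) validate_tet_mesh(mesh)
  mesh
}

validate_tet_mesh <- function(mesh) {
  el <- mesh$elements
  if (min(el) < 1 || max(el) > nrow(mesh$nodes))
    stop_input("element connectivity references missing nodes")
  if (!all(seq_len(nrow(mesh$nodes)) %in% el))
    stop_input("mesh contains nodes referenced by no element")
  vol <- tet_volumes_cpp(mesh$nodes, el[, 1:4, drop = FALSE])
  if (any(vol <= 0))
    rlang::abort(sprintf("inverted or degenerate element(s): %s",
                         paste(utils::head(which(vol <= 0), 5),
                               collapse = ", ")),
                 class = "spinefe_mesh_quality")
  if (mesh$order == 10L) {
    pair <- tet10_edge_pairs()
    for (m in seq_len(6)) {
      a <- el[, pair[m, 1]]; b <- el[, pair[m, 2]]; mid <- el[, 4 + m]
      gap <- abs(mesh$nodes[mid, , drop = FALSE] -
                   (mesh$nodes[a, , drop = FALSE] +
                      mesh$nodes[b, , drop = FALSE]) / 2)
      if (max(gap) > 1e-9)
        stop_input("tet10 midside nodes must lie at edge midpoints (within 1e-9 mm)")
    }
  }
  invisible(mesh)
}

# local corner pairs of the six tet10 edges, VTK order
tet10_edge_pairs <- function() {
  matrix(c(1, 2,  2, 3,  1, 3,  1, 4,  2, 4,  3, 4),
         ncol = 2, byrow = TRUE)
}

#' @export
print.spinefe_tet_mesh <- function(x, ...) {
  cat(sprintf("<tet mesh> %d nodes, %d tet%d elements\n",
              nrow(x$nodes), nrow(x$elements), x$order))
  if (length(x$element_sets))
    cat("  element sets:", paste(names(x$element_sets), collapse = ", "),
        "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

element_in_sets <- function(mesh, set_names) {
  out <- rep(FALSE, nrow(mesh$elements))
  for (nm in set_names)
    out[mesh$element_sets[[nm]]] <- TRUE
  out
}

disc_set_names <- function(mesh) {
  grep("^disc", names(mesh$element_sets), value = TRUE)
}

#' Element volumes (mm^3)
#' @param mesh a [tet_mesh()].
#' @export
element_volumes <- function(mesh) {
  tet_volumes_cpp(mesh$nodes, mesh$elements[, 1:4, drop = FALSE])
}

#' Promote a tet4 mesh to tet10
#'
#' Inserts a midside node at the midpoint of every unique element edge.
#' Node and element sets are carried over; node sets are extended with
#' the midside nodes whose both edge endpoints belong to the set (so
#' surface node sets stay surface node sets).
#'
#' @param mesh a tet4 [tet_mesh()].
#' @return A tet10 mesh.
#' @export
tet4_to_tet10 <- function(mesh) {
  stopifnot(inherits(mesh, "spinefe_tet_mesh"))
  if (mesh$order != 4L) stop_input("mesh is not tet4")
  el <- mesh$elements
  pair <- tet10_edge_pairs()
  ea <- c(); eb <- c()
  for (m in 1:6) { ea <- c(ea, el[, pair[m, 1]]); eb <- c(eb, el[, pair[m, 2]]) }
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  ids <- match(key, key[uk])            # edge index per (element, edge)
  nn <- nrow(mesh$nodes)
  mids <- (mesh$nodes[lo[uk], , drop = FALSE] +
             mesh$nodes[hi[uk], , drop = FALSE]) / 2
  el10 <- cbind(el, matrix(nn + ids, nrow(el), 6))
  node_sets <- lapply(mesh$node_sets, function(s) {
    on_set <- (lo[uk] %in% s) & (hi[uk] %in% s)
    c(s, nn + which(on_set))
  })
  tet_mesh(rbind(mesh$nodes, mids), el10,
           element_sets = mesh$element_sets, node_sets = node_sets,
           E = mesh$E, nu = mesh$nu)
}

#' Boundary surface of a tet mesh
#'
#' Faces belonging to exactly one element. Returns the corner triangles,
#' the owning element of each face and (for tet10) the 6-node faces
#' including midside nodes.
#'
#' @param mesh a [tet_mesh()].
#' @return A list with `tri` (f x 3 corner node ids), `elem` (owning
#'   element per face), `tri6` (f x 6, tet10 only), and `nodes` (unique
#'   surface node ids, midsides included).
#' @export
mesh_surface <- function(mesh) {
  el <- mesh$elements
  faces_local <- matrix(c(1, 3, 2,  1, 2, 4,  2, 3, 4,  1, 4, 3),
                        ncol = 3, byrow = TRUE)
  # local midside index (column in the tet10 row) for each face edge
  mid_of_pair <- matrix(0L, 4, 4)
  pair <- tet10_edge_pairs()
  for (m in 1:6) {
    mid_of_pair[pair[m, 1], pair[m, 2]] <- 4L + m
    mid_of_pair[pair[m, 2], pair[m, 1]] <- 4L + m
  }
  ne <- nrow(el)
  fid <- matrix(0L, 4 * ne, 3)
  owner <- integer(4 * ne); lface <- integer(4 * ne)
  for (f in 1:4) {
    rows <- (f - 1) * ne + seq_len(ne)
    fid[rows, ] <- el[, faces_local[f, ], drop = FALSE]
    owner[rows] <- seq_len(ne); lface[rows] <- f
  }
  keym <- t(apply(fid, 1, sort))
  key <- paste(keym[, 1], keym[, 2], keym[, 3])
  cnt <- table(key)
  bnd <- cnt[key] == 1
  tri <- fid[bnd, , drop = FALSE]
  owner <- owner[bnd]; lface <- lface[bnd]
  tri6 <- NULL
  if (mesh$order == 10L) {
    tri6 <- matrix(0L, nrow(tri), 6)
    tri6[, 1:3] <- tri
    for (k in 1:3) {
      la <- faces_local[lface, k]
      lb <- faces_local[lface, k %% 3 + 1]
      lm <- mid_of_pair[cbind(la, lb)]
      tri6[, 3 + k] <- el[cbind(owner, lm)]
    }
  }
  nodes <- sort(unique(c(tri, tri6)))
  list(tri = tri, elem = owner, tri6 = tri6, nodes = nodes)
}

#' Structured box mesh (tests and verification problems)
#'
#' A rectangular box split into a structured hex grid, each hex split
#' into six tetrahedra around its main diagonal (a conforming Kuhn
#' subdivision).
#'
#' @param lx,ly,lz box edge lengths (mm).
#' @param nx,ny,nz cells per direction.
#' @param order 4 or 10.
#' @return A [tet_mesh()] with node sets `base` (z = 0) and `top`
#'   (z = lz).
#' @export
box_tet_mesh <- function(lx = 10, ly = 10, lz = 10, nx = 2, ny = 2,
                         nz = 2, order = 4) {
  gx <- seq(0, lx, length.out = nx + 1)
  gy <- seq(0, ly, length.out = ny + 1)
  gz <- seq(0, lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1) * (j - 1) + (nx + 1) * (ny + 1) * (k - 1)
  cells <- expand.grid(i = 1:nx, j = 1:ny, k = 1:nz)
  el <- kuhn_tets(cells$i, cells$j, cells$k, nid)
  mesh <- tet_mesh(nodes, el,
                   node_sets = list(
                     base = which(abs(nodes[, 3]) < 1e-12),
                     top = which(abs(nodes[, 3] - lz) < 1e-12)))
  if (order == 10) mesh <- tet4_to_tet10(mesh) else mesh
}

# Kuhn 6-tet subdivision of hex cells (i, j, k): conforming across the
# structured grid because face diagonals are translation-invariant.
kuhn_tets <- function(i, j, k, nid) {
  v <- function(dx, dy, dz) nid(i + dx, j + dy, k + dz)
  # the 6 path tetrahedra 000 -> e_p1 -> e_p1+e_p2 -> 111
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ebit <- diag(3)
  out <- vector("list", 6)
  for (p in seq_along(perms)) {
    b1 <- ebit[perms[[p]][1], ]
    b2 <- b1 + ebit[perms[[p]][2], ]
    t0 <- v(0, 0, 0)
    t1 <- v(b1[1], b1[2], b1[3])
    t2 <- v(b2[1], b2[2], b2[3])
    t3 <- v(1, 1, 1)
    # even permutations give positive volume; swap to fix odd ones
    if (p %in% c(2, 3, 6)) { tmp <- t1; t1 <- t2; t2 <- tmp }
    out[[p]] <- cbind(t0, t1, t2, t3)
  }
  el <- do.call(rbind, out)
  dimnames(el) <- NULL
  el
}
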