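#' Boundary conditions for a spine-segment solve
#'
#' The loading replicates a pot-driven test: the base node set is fully
#' fixed, while the top node set is rigidly tied to a pilot point SP
#' (the marker-cluster centroid) whose rigid-body motion is prescribed.
#' Tied nodes move exactly as
#' `u_i = R (x_i - SP) + T - (x_i - SP)` for pilot motion `(R, T)`
#' expressed about SP.
#'
#' @param fixed_nodes node ids with all translations zero.
#' @param tied_nodes node ids rigidly driven by the pilot.
#' @param pilot length-3 pilot point SP (mm).
#' @param pilot_motion a [rigid_transform()] (its `about` is forced to
#'   the pilot), or `NULL` for no prescribed motion.
#' @param axial_dir unit vector of the axial (cranio-caudal) direction;
#'   default +z (SI).
#' @param target_force optional axial force target (N) carried along for
#'   calibration.
#' @return An object of class `spinefe_bcs`.
#' @export
boundary_conditions <- function(fixed_nodes, tied_nodes, pilot,
                                pilot_motion = NULL,
                                axial_dir = c(0, 0, 1),
                                target_force = NULL) {
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  tied_nodes <- sort(unique(as.integer(tied_nodes)))
  if (length(intersect(fixed_nodes, tied_nodes)) > 0)
    stop_input("fixed and tied node sets must be disjoint")
  if (!is.null(pilot_motion)) {
    if (!inherits(pilot_motion, "spinefe_rigid_transform"))
      rlang::abort("`pilot_motion` must be a rigid_transform",
                   class = "spinefe_invalid_transform")
    if (length(tied_nodes) == 0)
      stop_input("tied node set must be non-empty when a pilot motion is set")
    pilot_motion$about <- as.numeric(pilot)
  }
  axial_dir <- as.numeric(axial_dir)
  axial_dir <- axial_dir / sqrt(sum(axial_dir^2))
  structure(list(fixed_nodes = fixed_nodes, tied_nodes = tied_nodes,
                 pilot = as.numeric(pilot), pilot_motion = pilot_motion,
                 axial_dir = axial_dir, target_force = target_force),
            class = "spinefe_bcs")
}

#' Assemble the global stiffness operator
#'
#' Standard isoparametric small-strain assembly (tet4: exact constant-B
#' integration; tet10: 4-point Gauss, exact for straight-edged
#' elements). Returns a symmetric sparse matrix; for an unconstrained
#' connected mesh it is positive semi-definite with the 6-dimensional
#' rigid-body null space.
#'
#' @param mesh a [tet_mesh()] with materials assigned.
#' @param elements optional element subset to assemble (used to split
#'   bone and disc stiffness for the calibration).
#' @param E,nu optional overrides for the subset.
#' @return A `Matrix::dsCMatrix` of size `3n x 3n`.
#' @export
fe_assemble <- function(mesh, elements = NULL, E = NULL, nu = NULL) {
  stopifnot(inherits(mesh, "spinefe_tet_mesh"))
  idx <- if (is.null(elements)) seq_len(nrow(mesh$elements)) else elements
  Ee <- if (is.null(E)) mesh$E[idx] else rep_len(E, length(idx))
  nue <- if (is.null(nu)) mesh$nu[idx] else rep_len(nu, length(idx))
  if (any(!is.finite(Ee)) || any(Ee <= 0))
    stop_input("all assembled elements need a finite positive modulus; run map_materials()/set disc material first")
  if (any(!is.finite(nue)) || any(nue < 0) || any(nue >= 0.5))
    stop_input("Poisson ratios must lie in [0, 0.5)")
  tr <- asm_stiffness_cpp(mesh$nodes,
                          mesh$elements[idx, , drop = FALSE], Ee, nue)
  ndof <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(ndof, ndof), symmetric = TRUE)
}

node_dofs <- function(nodes_idx) {
  as.vector(t(outer(3L * (as.integer(nodes_idx) - 1L), 1:3, "+")))
}

#' Solve with directly prescribed nodal displacements
#'
#' The workhorse behind [fe_solve()], also useful for verification
#' problems (patch tests). Constraints are enforced by exact
#' elimination of the prescribed degrees of freedom; reactions are the
#' rows of `K u` at the prescribed nodes.
#'
#' @param mesh a [tet_mesh()].
#' @param nodes node ids with prescribed displacement.
#' @param U_presc length(nodes) x 3 matrix of prescribed displacements
#'   (mm).
#' @param K optional pre-assembled stiffness.
#' @return list with `U` (n x 3), `reactions` (length(nodes) x 3) and
#'   `residual` (free-dof residual norm).
#' @export
fe_solve_dirichlet <- function(mesh, nodes, U_presc, K = NULL) {
  if (length(nodes) == 0)
    rlang::abort("system is singular: no constrained nodes",
                 class = "spinefe_rank_error")
  if (is.null(K)) K <- fe_assemble(mesh)
  n <- nrow(mesh$nodes)
  U_presc <- as_points3(U_presc)
  stopifnot(nrow(U_presc) == length(nodes))
  cd <- node_dofs(nodes)
  uc <- as.vector(t(U_presc))
  fd <- setdiff(seq_len(3L * n), cd)
  Uv <- numeric(3L * n)
  Uv[cd] <- uc
  if (length(fd) > 0) {
    Kff <- K[fd, fd]
    rhs <- -K[fd, cd, drop = FALSE] %*% uc
    ch <- tryCatch(suppressWarnings(
      Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)),
      error = function(e)
        rlang::abort(
          "stiffness is singular after constraints (insufficient supports?)",
          class = "spinefe_rank_error", parent = e))
    Uv[fd] <- as.vector(Matrix::solve(ch, rhs))
    if (any(!is.finite(Uv[fd])))
      rlang::abort("stiffness is singular after constraints (insufficient supports?)",
                   class = "spinefe_rank_error")
  }
  U <- matrix(Uv, n, 3, byrow = TRUE)
  r <- as.vector(K %*% Uv)
  residual <- if (length(fd)) max(abs(r[fd])) else 0
  reactions <- matrix(r[cd], ncol = 3, byrow = TRUE)
  list(U = U, reactions = reactions, residual = residual)
}

#' Apply boundary conditions and solve the linear elastic system
#'
#' Fixed nodes are clamped; tied nodes get the exact rigid-body
#' displacement of the pilot motion (finite rotation, not linearised).
#' Reactions are reported at both sets; the axial resultant is the
#' component of the fixed-set (base) reaction along the axial
#' direction.
#'
#' @param mesh a [tet_mesh()] with materials assigned.
#' @param bcs a [boundary_conditions()].
#' @param K optional pre-assembled stiffness (reused across disc
#'   calibration iterations).
#' @return An object of class `spinefe_solution`: nodal displacements
#'   `U` (mm), per-set reactions (N), `axial_force` (N), element
#'   `strain`/`stress`, and the free-dof equilibrium residual.
#' @export
fe_solve <- function(mesh, bcs, K = NULL) {
  stopifnot(inherits(bcs, "spinefe_bcs"))
  nodes <- c(bcs$fixed_nodes, bcs$tied_nodes)
  Uc <- matrix(0, length(nodes), 3)
  if (!is.null(bcs$pilot_motion) && length(bcs$tied_nodes) > 0) {
    xt <- mesh$nodes[bcs$tied_nodes, , drop = FALSE]
    Uc[length(bcs$fixed_nodes) + seq_along(bcs$tied_nodes), ] <-
      transform_points(bcs$pilot_motion, xt) - xt
  }
  sol <- fe_solve_dirichlet(mesh, nodes, Uc, K = K)
  nf <- length(bcs$fixed_nodes)
  rf <- sol$reactions[seq_len(nf), , drop = FALSE]
  rt <- sol$reactions[nf + seq_along(bcs$tied_nodes), , drop = FALSE]
  strain <- element_strains_cpp(mesh$nodes, mesh$elements, sol$U)
  stress <- stress_from_strain(strain, mesh$E, mesh$nu)
  structure(list(
    U = sol$U,
    reactions_fixed = rf, reactions_tied = rt,
    fixed_nodes = bcs$fixed_nodes, tied_nodes = bcs$tied_nodes,
    axial_dir = bcs$axial_dir,
    axial_force = sum(rf %*% bcs$axial_dir),
    strain = strain, stress = stress,
    residual = sol$residual, pilot = bcs$pilot),
    class = "spinefe_solution")
}

stress_from_strain <- function(strain, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  tr <- strain[, 1] + strain[, 2] + strain[, 3]
  cbind(lam * tr + 2 * mu * strain[, 1],
        lam * tr + 2 * mu * strain[, 2],
        lam * tr + 2 * mu * strain[, 3],
        mu * strain[, 4], mu * strain[, 5], mu * strain[, 6])
}

#' @export
print.spinefe_solution <- function(x, ...) {
  cat(sprintf("<FE solution> %d nodes, max |U| = %.4f mm\n",
              nrow(x$U), max(sqrt(rowSums(x$U^2)))))
  cat(sprintf("  axial force at base: %.4f N (free-dof residual %.3g)\n",
              x$axial_force, x$residual))
  invisible(x)
}

#' Resultant force and moment of a constrained node set
#'
#' @param solution a [fe_solve()] result.
#' @param set `"fixed"` or `"tied"`.
#' @param mesh the solved mesh (for moment arms).
#' @param about reference point for the moment (mm); defaults to the
#'   centroid of the set.
#' @return list with `force` (N), `moment` (N mm) and `about`.
#' @export
reaction <- function(solution, mesh, set = c("fixed", "tied"),
                     about = NULL) {
  set <- match.arg(set)
  ids <- switch(set, fixed = solution$fixed_nodes,
                tied = solution$tied_nodes)
  if (length(ids) == 0)
    rlang::abort(sprintf("the %s set is empty/unconstrained", set),
                 class = "spinefe_contract_error")
  r <- switch(set, fixed = solution$reactions_fixed,
              tied = solution$reactions_tied)
  x <- mesh$nodes[ids, , drop = FALSE]
  if (is.null(about)) about <- colMeans(x)
  arm <- sweep(x, 2, about)
  mom <- c(sum(arm[, 2] * r[, 3] - arm[, 3] * r[, 2]),
           sum(arm[, 3] * r[, 1] - arm[, 1] * r[, 3]),
           sum(arm[, 1] * r[, 2] - arm[, 2] * r[, 1]))
  list(force = colSums(r), moment = mom, about = about)
}

#' @export
tidy.spinefe_solution <- function(x, ...) {
  tibble::tibble(node = seq_len(nrow(x$U)),
                 ux = x$U[, 1], uy = x$U[, 2], uz = x$U[, 3],
                 magnitude = sqrt(rowSums(x$U^2)))
}

#' @export
glance.spinefe_solution <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$U),
    axial_force = x$axial_force,
    max_displacement = max(sqrt(rowSums(x$U^2))),
    equilibrium_residual = x$residual)
}

#' Interpolate the displacement field at arbitrary points
#'
#' Locates each query point in the tetrahedral mesh (via the elements
#' incident to its nearest corner nodes), computes barycentric
#' coordinates in the corner tetrahedron and evaluates the element
#' shape functions (quadratic for tet10). Points slightly outside the
#' mesh (e.g. probe points on the smooth cylinder surface vs the
#' polygonal mesh boundary) are clamped to the closest element within
#' `tol_outside`.
#'
#' @param mesh a [tet_mesh()].
#' @param solution a [fe_solve()] result (or any n x 3 nodal field as
#'   `U`).
#' @param points m x 3 query coordinates (mm).
#' @param tol_outside maximum admissible barycentric excursion outside
#'   an element (default 0.1).
#' @return m x 3 matrix of interpolated displacements.
#' @export
interpolate_displacement <- function(mesh, solution, points,
                                     tol_outside = 0.1) {
  U <- if (is.matrix(solution)) solution else solution$U
  points <- as_points3(points)
  corners <- mesh$elements[, 1:4, drop = FALSE]
  ncorner <- max(corners)
  # elements incident to each corner node
  inc <- split(rep(seq_len(nrow(corners)), 4), as.vector(corners))
  nn <- RANN::nn2(mesh$nodes[seq_len(ncorner), , drop = FALSE],
                  points, k = min(4L, ncorner))
  out <- matrix(NA_real_, nrow(points), 3)
  for (q in seq_len(nrow(points))) {
    cand <- unique(unlist(inc[as.character(nn$nn.idx[q, ])]))
    best <- NULL; best_def <- Inf
    for (e in cand) {
      x <- mesh$nodes[corners[e, ], , drop = FALSE]
      A <- t(x[1:3, , drop = FALSE]) - x[4, ]
      b <- tryCatch(solve(A, points[q, ] - x[4, ]),
                    error = function(err) NULL)
      if (is.null(b)) next
      bary <- c(b, 1 - sum(b))
      deficit <- max(0, -min(bary), max(bary) - 1)
      if (deficit < best_def) { best_def <- deficit; best <- list(e = e, bary = bary) }
      if (deficit == 0) break
    }
    if (is.null(best) || best_def > tol_outside) next
    bary <- pmin(pmax(best$bary, 0), 1)
    bary <- bary / sum(bary)
    en <- mesh$elements[best$e, ]
    if (mesh$order == 4L) {
      N <- bary
    } else {
      pair <- tet10_edge_pairs()
      N <- c(bary * (2 * bary - 1),
             4 * bary[pair[, 1]] * bary[pair[, 2]])
    }
    out[q, ] <- as.vector(N %*% U[en, , drop = FALSE])
  }
  out
}
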