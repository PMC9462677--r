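# stiffness assembly, constraint handling, reactions and equilibrium

single_tet4 <- function(E = 1000, nu = 0.3) {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1), E = E, nu = nu)
}

test_that("a single tet4 operator is symmetric with a rigid-body null space", {
  K <- as.matrix(fe_assemble(single_tet4()))
  expect_equal(dim(K), c(12L, 12L))
  expect_equal(K, t(K), tolerance = 1e-14)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-9 * max(ev)), 6)
  expect_true(all(ev > -1e-9 * max(ev)))
  # rigid translation produces zero force
  u <- rep(c(1, -2, 3), 4)
  expect_lt(max(abs(K %*% u)), 1e-10 * max(abs(K)))
})

test_that("the operator is linear in the modulus", {
  K1 <- fe_assemble(single_tet4(E = 123))
  K2 <- fe_assemble(single_tet4(E = 246))
  expect_equal(as.matrix(K2), 2 * as.matrix(K1), tolerance = 1e-14)
})

test_that("tet10 elements pass the patch test to 1e-9 relative", {
  mesh <- box_tet_mesh(3, 2, 2, 2, 2, 2, order = 10)
  mesh$E[] <- 7; mesh$nu[] <- 0.3
  surf <- mesh_surface(mesh)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -2e-3, 5e-4,
                1e-4, 6e-4, 1.5e-3), 3, 3)
  sol <- fe_solve_dirichlet(mesh, surf$nodes,
                            mesh$nodes[surf$nodes, ] %*% t(A))
  U_exact <- mesh$nodes %*% t(A)
  expect_lt(max(abs(sol$U - U_exact)) / max(abs(U_exact)), 1e-9)
  # constant strain reproduced at every element
  eps <- element_strains_cpp(mesh$nodes, mesh$elements, sol$U)
  expect_equal(eps[, 1], rep(A[1, 1], nrow(eps)), tolerance = 1e-9)
  expect_equal(eps[, 4], rep(A[1, 2] + A[2, 1], nrow(eps)),
               tolerance = 1e-9)
})

test_that("uniaxial compression of a cube matches the rod formula", {
  for (ord in c(4, 10)) {
    mesh <- box_tet_mesh(10, 10, 10, 2, 2, 2, order = ord)
    mesh$E[] <- 100; mesh$nu[] <- 0
    bcs <- boundary_conditions(
      mesh$node_sets$base, mesh$node_sets$top, pilot = c(5, 5, 10),
      pilot_motion = rigid_transform(t = c(0, 0, -0.1)))
    sol <- fe_solve(mesh, bcs)
    # F = E A delta / L = 100 * 100 * 0.1 / 10 = 100 N
    expect_equal(abs(sol$axial_force), 100, tolerance = 1e-8)
    r <- reaction(sol, mesh, "fixed")
    expect_equal(abs(r$force[3]), 100, tolerance = 1e-6)
    expect_equal(r$force[1:2], c(0, 0), tolerance = 1e-8)
    # base and pilot reactions are equal and opposite
    rt <- reaction(sol, mesh, "tied")
    expect_equal(r$force + rt$force, c(0, 0, 0), tolerance = 1e-8)
  }
})

test_that("identity pilot motion yields the zero solution", {
  mesh <- box_tet_mesh(10, 10, 10, 2, 2, 2, order = 4)
  mesh$E[] <- 50; mesh$nu[] <- 0.25
  bcs <- boundary_conditions(mesh$node_sets$base, mesh$node_sets$top,
                             pilot = c(5, 5, 10),
                             pilot_motion = rigid_transform())
  sol <- fe_solve(mesh, bcs)
  expect_lt(max(abs(sol$U)), 1e-12)
  expect_lt(max(abs(sol$reactions_fixed)), 1e-9)
  r0 <- reaction(sol, mesh, "fixed")
  expect_equal(r0$force, c(0, 0, 0), tolerance = 1e-9)
})

test_that("insufficient constraints raise a rank error", {
  mesh <- box_tet_mesh(4, 4, 4, 1, 1, 1, order = 4)
  mesh$E[] <- 10; mesh$nu[] <- 0.3
  expect_error(fe_solve_dirichlet(mesh, integer(0), matrix(0, 0, 3)),
               class = "spinefe_rank_error")
  # a single constrained node leaves free rotations
  expect_error(
    fe_solve_dirichlet(mesh, 1L, matrix(0, 1, 3)),
    class = "spinefe_rank_error")
})

test_that("equilibrium holds on the phantom solve", {
  ph <- phantom_fix()
  sol <- ph$solution
  all_r <- rbind(sol$reactions_fixed, sol$reactions_tied)
  expect_lt(max(abs(colSums(all_r))), 1e-8 * max(abs(all_r)))
  # free-dof residual bounded relative to the largest reaction
  expect_lt(sol$residual, 1e-8 * max(abs(all_r)))
})

test_that("the solution is invariant under node renumbering", {
  mesh <- box_tet_mesh(6, 6, 9, 2, 2, 3, order = 10)
  withr::local_seed(11)
  mesh$E <- stats::runif(nrow(mesh$elements), 100, 5000)
  mesh$nu[] <- 0.3
  motion <- rigid_transform(rotation_axis_angle(c(1, 0.2, 0), 0.02),
                            t = c(0.05, -0.02, -0.1),
                            about = c(3, 3, 9))
  bcs <- boundary_conditions(mesh$node_sets$base, mesh$node_sets$top,
                             pilot = c(3, 3, 9), pilot_motion = motion)
  sol <- fe_solve(mesh, bcs)
  perm <- sample(nrow(mesh$nodes))
  nodes2 <- mesh$nodes; nodes2[perm, ] <- mesh$nodes
  el2 <- matrix(perm[mesh$elements], nrow(mesh$elements))
  mesh2 <- tet_mesh(nodes2, el2,
                    node_sets = lapply(mesh$node_sets,
                                       function(s) perm[s]),
                    E = mesh$E, nu = mesh$nu)
  bcs2 <- boundary_conditions(mesh2$node_sets$base,
                              mesh2$node_sets$top,
                              pilot = c(3, 3, 9), pilot_motion = motion)
  sol2 <- fe_solve(mesh2, bcs2)
  expect_equal(sol2$U[perm, ], sol$U,
               tolerance = 1e-8)
  expect_equal(sol2$axial_force, sol$axial_force, tolerance = 1e-8)
})

test_that("displacement interpolation reproduces affine fields", {
  mesh <- box_tet_mesh(6, 6, 6, 2, 2, 2, order = 10)
  A <- matrix(c(2e-3, 1e-4, 0, -1e-4, 1e-3, 2e-4, 0, 5e-4, -2e-3),
              3, 3)
  U <- mesh$nodes %*% t(A)
  withr::local_seed(3)
  p <- matrix(stats::runif(30, 0.2, 5.8), 10, 3)
  expect_equal(interpolate_displacement(mesh, U, p), p %*% t(A),
               tolerance = 1e-10)
})

test_that("tidy and glance summarise a solution", {
  ph <- coarse_phantom_fix()
  td <- tidy(ph$solution)
  expect_equal(nrow(td), nrow(ph$mesh$nodes))
  gl <- glance(ph$solution)
  expect_equal(gl$axial_force, ph$solution$axial_force)
  expect_gt(gl$max_displacement, 1)
})
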