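# density calibration chain and element-wise material mapping

test_that("HU-to-QCT-density calibration reproduces the printed affine map", {
  expect_identical(hu_to_rho_qct(0), -0.016404)
  # frozen from an independent evaluation of the printed coefficients
  expect_equal(hu_to_rho_qct(1000), 0.835236, tolerance = 1e-12)
  # affine slope: consecutive HU differ by exactly the calibration slope
  hu <- c(-750, 0, 137.5, 2000)
  expect_equal(hu_to_rho_qct(hu + 1) - hu_to_rho_qct(hu),
               rep(0.00085164, 4), tolerance = 1e-9)
  expect_error(hu_to_rho_qct(c(1, NA)), class = "spinefe_invalid_input")
  # inverse mapping closes the loop
  expect_equal(rho_qct_to_hu(hu_to_rho_qct(hu)), hu, tolerance = 1e-9)
})

test_that("density-to-modulus chain matches independently computed values", {
  z <- rho_qct_to_modulus(0)
  expect_identical(z$rho_ash, 0.079)
  # unit apparent density makes the power term one
  u <- rho_qct_to_modulus((0.6 - 0.079) / 0.877)
  expect_equal(u$rho_app, 1, tolerance = 1e-12)
  expect_equal(u$E, 4730, tolerance = 1e-9)
  # full chain at 1000 HU, frozen from an independent calculator
  m <- rho_qct_to_modulus(0.835236)
  expect_equal(m$rho_ash, 0.811501972, tolerance = 1e-12)
  expect_equal(m$rho_app, 1.3525032866666666, tolerance = 1e-12)
  expect_equal(m$E, 7575.947112380489, tolerance = 1e-10)
})

test_that("modulus floor clamps non-physical densities with a warning", {
  expect_warning(res <- rho_qct_to_modulus(-2), "clamped")
  expect_identical(res$E, 0.01)
  # air-like HU maps to the floor through the fused evaluation
  expect_warning(air <- hu_to_modulus(-1000))
  expect_identical(air$E, 0.01)
})

test_that("mapped modulus is monotone in HU and composition-consistent", {
  withr::local_seed(42)
  hu <- sort(stats::runif(50, 100, 2500))
  E <- hu_to_modulus(hu)$E
  expect_true(all(diff(E) > 0))
  # fused evaluation equals the two-step chain to machine precision
  two_step <- rho_qct_to_modulus(hu_to_rho_qct(hu))
  expect_identical(hu_to_modulus(hu)$E, two_step$E)
})

test_that("constant grids map the voxel modulus onto every element", {
  grid <- uniform_grid(1000)
  for (ord in c(4, 10)) {
    mesh <- box_tet_mesh(10, 10, 10, 2, 2, 2, order = ord)
    mesh <- map_materials(mesh, grid)
    expect_equal(mesh$E, rep(7575.947112380489, nrow(mesh$elements)),
                 tolerance = 1e-9)
    expect_equal(mesh$nu, rep(0.3, nrow(mesh$elements)))
  }
})

test_that("two-region grids assign each element its region's modulus", {
  # brute-force oracle: elements lie entirely on one side of z = 5,
  # so their volume average must equal that side's voxel modulus
  lo <- uniform_grid(400)
  hi_vals <- lo$values
  zc <- lo$origin[3] + (seq_len(lo$dims[3]) - 1) * lo$spacing[3]
  hi_vals[, , zc >= 5] <- 1500
  grid <- density_grid(hi_vals, lo$origin, lo$spacing, lo$dims, "HU")
  mesh <- box_tet_mesh(10, 10, 10, 2, 2, 2, order = 4)
  mesh <- map_materials(mesh, grid)
  cz <- (mesh$nodes[mesh$elements[, 1], 3] +
           mesh$nodes[mesh$elements[, 2], 3] +
           mesh$nodes[mesh$elements[, 3], 3] +
           mesh$nodes[mesh$elements[, 4], 3]) / 4
  E_lo <- hu_to_modulus(400)$E
  E_hi <- hu_to_modulus(1500)$E
  # elements fully below the interface (max node z <= 5)
  zmax <- apply(matrix(mesh$nodes[mesh$elements[, 1:4], 3],
                       ncol = 4), 1, max)
  zmin <- apply(matrix(mesh$nodes[mesh$elements[, 1:4], 3],
                       ncol = 4), 1, min)
  # one-voxel margin: trilinear sampling mixes values across the
  # interface voxel layer
  expect_equal(mesh$E[zmax <= 4], rep(E_lo, sum(zmax <= 4)),
               tolerance = 1e-9)
  expect_equal(mesh$E[zmin >= 6], rep(E_hi, sum(zmin >= 6)),
               tolerance = 1e-9)
  expect_true(all(mesh$E >= E_lo - 1e-9 & mesh$E <= E_hi + 1e-9))
})

test_that("all-air grids floor every element and report goes to CSV", {
  grid <- uniform_grid(-1000)
  mesh <- box_tet_mesh(10, 10, 10, 2, 2, 2, order = 4)
  mesh <- map_materials(mesh, grid)
  expect_equal(mesh$E, rep(0.01, nrow(mesh$elements)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_material_report(mesh, path)
  rep <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(rep), nrow(mesh$elements))
  expect_true(all(c("element", "rho_qct", "rho_ash", "rho_app", "E")
                  %in% names(rep)))
})

test_that("trilinear grid sampling is exact for affine voxel fields", {
  # an affine field is reproduced exactly by trilinear interpolation
  dims <- c(6L, 5L, 4L)
  xs <- seq(0, 5); ys <- seq(0, 4); zs <- seq(0, 3)
  vals <- outer(outer(2 * xs, 3 * ys, "+"), 5 * zs, "+") + 1
  grid <- density_grid(vals, origin = c(0, 0, 0),
                       spacing = c(1, 1, 1), dims = dims,
                       value_kind = "rho_qct")
  withr::local_seed(7)
  p <- cbind(stats::runif(20, 0, 5), stats::runif(20, 0, 4),
             stats::runif(20, 0, 3))
  expect_equal(grid_sample(grid, p),
               2 * p[, 1] + 3 * p[, 2] + 5 * p[, 3] + 1,
               tolerance = 1e-12)
  # outside the voxel-centre hull
  expect_true(is.na(grid_sample(grid, rbind(c(-1, 0, 0)))))
})
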