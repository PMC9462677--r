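# spherical averaging, Cook's screening, regression metrics,
# error fields and Bland-Altman agreement

# minimal mesh/solution pair with DIC-style cloud for pairing tests
pairing_setup <- function() {
  mesh <- box_tet_mesh(10, 10, 10, 2, 2, 2, order = 4)
  U <- mesh$nodes %*% t(matrix(c(0.01, 0, 0, 0, 0.02, 0,
                                 0, 0, -0.03), 3, 3, byrow = TRUE))
  sol <- list(U = U)
  list(mesh = mesh, sol = sol)
}

test_that("spherical averaging pairs nodes with in-radius cloud means", {
  s <- pairing_setup()
  nodes <- s$mesh$node_sets$top[1:4]
  xq <- s$mesh$nodes[nodes, ]
  cfg <- validation_config(radius = 1)
  # one cloud point exactly at each node: the mean is that vector
  f1 <- surface_field(xq, matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE))
  p1 <- pair_and_average(s$mesh, s$sol, f1, nodes, cfg)
  expect_equal(nrow(p1), 4)
  expect_equal(p1$u_dic_x, rep(1, 4))
  expect_equal(p1$n_cloud, rep(1L, 4))
  # two points in the sphere average component-wise: (1,0,0),(3,0,0)
  f2 <- surface_field(rbind(xq[1, ] + c(0.2, 0, 0),
                            xq[1, ] - c(0.2, 0, 0)),
                      rbind(c(1, 0, 0), c(3, 0, 0)))
  p2 <- pair_and_average(s$mesh, s$sol, f2, nodes[1], cfg)
  expect_equal(c(p2$u_dic_x, p2$u_dic_y, p2$u_dic_z), c(2, 0, 0))
  # constant fields average to the constant for any radius
  withr::local_seed(2)
  cl <- matrix(stats::runif(60, 0, 10), 20, 3)
  fc <- surface_field(cl, matrix(rep(c(0.4, -0.2, 0.1), 20), 20,
                                 byrow = TRUE))
  for (R in c(3, 6, 10)) {
    pc <- pair_and_average(s$mesh, s$sol, fc, nodes,
                           validation_config(radius = R))
    if (nrow(pc) > 0) {
      expect_equal(pc$u_dic_x, rep(0.4, nrow(pc)))
      expect_equal(pc$u_dic_z, rep(0.1, nrow(pc)))
      # brute-force neighbourhood count oracle
      d2 <- outer(rowSums(s$mesh$nodes[pc$node, , drop = FALSE]^2),
                  rowSums(cl^2), "+") -
        2 * s$mesh$nodes[pc$node, , drop = FALSE] %*% t(cl)
      expect_equal(pc$n_cloud, rowSums(sqrt(pmax(d2, 0)) <= R + 1e-9))
    }
  }
  # far-away cloud: configuration error
  ffar <- surface_field(xq + 100, matrix(0, 4, 3))
  expect_error(pair_and_average(s$mesh, s$sol, ffar, nodes, cfg),
               class = "spinefe_configuration_error")
})

test_that("Cook's-distance screening matches a leave-one-out oracle", {
  x <- c(1, 2, 3, 4, 10)
  y <- c(1, 2, 3, 4, 0)
  mask <- cooks_filter(x, y, multiplier = 4)
  expect_length(mask, 5)
  expect_identical(mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # oracle: Cook's D via explicit leave-one-out refits
  fit <- stats::lm(y ~ x)
  p <- 2; s2 <- sum(residuals(fit)^2) / (5 - p)
  D_loo <- vapply(1:5, function(i) {
    fi <- stats::lm(y[-i] ~ x[-i])
    pred_full <- fitted(fit)
    pred_loo <- cbind(1, x) %*% coef(fi)
    sum((pred_full - pred_loo)^2) / (p * s2)
  }, numeric(1))
  expect_identical(mask, !(D_loo > 4 * mean(D_loo)))
  # perfectly linear data: nothing removed
  expect_identical(cooks_filter(1:6, 2 * (1:6) + 1), rep(TRUE, 6))
  # fewer than 4 points: skipped with a warning
  expect_warning(m3 <- cooks_filter(1:3, c(1, 2, 9)), "skipped")
  expect_identical(m3, rep(TRUE, 3))
})

test_that("regression metrics are exact for identity and hand examples", {
  cfg <- validation_config(radius = 1)
  mkpairs <- function(dic, fem) {
    tibble::tibble(node = seq_len(nrow(dic)), x = 0, y = 0, z = 0,
                   n_cloud = 1L,
                   u_fem_x = fem[, 1], u_fem_y = fem[, 2],
                   u_fem_z = fem[, 3],
                   u_dic_x = dic[, 1], u_dic_y = dic[, 2],
                   u_dic_z = dic[, 3])
  }
  withr::local_seed(4)
  dic <- matrix(stats::rnorm(30), 10, 3)
  p_id <- mkpairs(dic, dic)
  for (cp in c("RL", "AP", "SI")) {
    m <- regress_component(p_id, cp, cfg)
    expect_equal(m$r_squared, 1, tolerance = 1e-12)
    expect_equal(m$slope, 1, tolerance = 1e-12)
    expect_equal(m$intercept, 0, tolerance = 1e-12)
    expect_equal(m$rmse, 0, tolerance = 1e-12)
    expect_equal(m$n_outliers_removed, 0)
  }
  # hand example: errors (0.1, 0.1, 0) -> Error% (10, 10, 0)
  dic5 <- matrix(rep(c(1, 1, 1), 5), 5, 3, byrow = TRUE) +
    outer(seq(0, 0.4, 0.1), c(1, 1, 1))
  fem5 <- dic5 + matrix(rep(c(-0.1, 0.1, 0), 5), 5, 3, byrow = TRUE)
  p5 <- mkpairs(dic5, fem5)
  mx <- regress_component(p5, "RL", cfg)
  expect_equal(mx$max_err, 0.1, tolerance = 1e-12)
  expect_equal(mx$rmse, 0.1, tolerance = 1e-12)
  expect_equal(mx$avg_err_pct,
               mean(100 * 0.1 / dic5[, 1]), tolerance = 1e-9)
  # %RMSE normalised by the max measured component in the region
  expect_equal(mx$pct_rmse, 100 * 0.1 / 1.4, tolerance = 1e-9)
  mz <- regress_component(p5, "SI", cfg)
  expect_equal(mz$rmse, 0, tolerance = 1e-12)
  expect_equal(mz$avg_err_pct, 0, tolerance = 1e-12)
  # %RMSE is invariant when both fields are scaled by k
  k <- 17
  mk <- regress_component(mkpairs(k * dic5, k * fem5), "RL", cfg)
  expect_equal(mk$pct_rmse, mx$pct_rmse, tolerance = 1e-9)
  expect_equal(mk$r_squared, mx$r_squared, tolerance = 1e-9)
  # zero-variance measurement: degenerate regression
  flat <- mkpairs(matrix(1, 5, 3), matrix(stats::rnorm(15), 5, 3))
  expect_error(regress_component(flat, "RL", cfg),
               class = "spinefe_degenerate_regression")
})

test_that("the error resultant dominates its components", {
  pairs <- tibble::tibble(
    u_dic_x = c(1, 0.3), u_dic_y = c(1, -0.2), u_dic_z = c(1, 0),
    u_fem_x = c(0.9, 0.3), u_fem_y = c(0.9, -0.2), u_fem_z = c(1, 0))
  d <- diff_field(pairs)
  expect_equal(d[1], sqrt(0.02), tolerance = 1e-12)
  expect_equal(d[2], 0)
  expect_true(all(d >= abs(pairs$u_dic_x - pairs$u_fem_x) - 1e-15))
})

test_that("Bland-Altman bias and limits behave for degenerate cases", {
  pairs <- tibble::tibble(
    u_dic_x = 1:5, u_dic_y = seq(0.1, 0.5, 0.1), u_dic_z = rep(2, 5),
    u_fem_x = 1:5, u_fem_y = seq(0.1, 0.5, 0.1), u_fem_z = rep(2, 5))
  ba <- bland_altman(pairs, "RL")
  expect_equal(ba$bias, 0)
  expect_equal(ba$data$difference, rep(0, 5))
  # constant offset: bias = delta, zero spread
  off <- pairs
  off$u_fem_x <- off$u_fem_x - 0.25
  bo <- bland_altman(off, "RL")
  expect_equal(bo$bias, 0.25)
  expect_equal(bo$loa_lower, 0.25)
  expect_equal(bo$loa_upper, 0.25)
  # magnitude flavour equals the error resultant
  bm <- bland_altman(off, type = "magnitude")
  expect_equal(bm$data$difference, diff_field(off), tolerance = 1e-12)
  expect_error(bland_altman(pairs[1, ], "RL"),
               class = "spinefe_invalid_input")
})

test_that("heteroscedastic noise leaves its trend in the agreement plot", {
  withr::local_seed(10)
  n <- 400
  dic <- matrix(stats::runif(3 * n, 0.5, 3), n, 3)
  # noise grows with the measured magnitude
  fem <- dic + matrix(stats::rnorm(3 * n), n, 3) * 0.05 * dic
  pairs <- tibble::tibble(
    u_dic_x = dic[, 1], u_dic_y = dic[, 2], u_dic_z = dic[, 3],
    u_fem_x = fem[, 1], u_fem_y = fem[, 2], u_fem_z = fem[, 3])
  ba <- bland_altman(pairs, type = "magnitude")
  trend <- stats::coef(stats::lm(abs(ba$data$difference) ~
                                   ba$data$mean))[2]
  expect_gt(trend, 0)
})

test_that("validating a solution against its own noise-free sample is exact", {
  ph <- coarse_phantom_fix()
  cl <- lapply(c("RoI_L2", "RoI_L3"), function(r)
    synth_dic_cloud(ph$solution, ph$mesh, r, ph$spec, noise = FALSE))
  names(cl) <- c("RoI_L2", "RoI_L3")
  val <- validate_displacements(ph$mesh, ph$solution, cl,
                                list("RoI_L2", "RoI_L3"),
                                validation_config(radius = 0.5))
  expect_equal(val$metrics$r_squared, rep(1, 6), tolerance = 1e-9)
  expect_equal(val$metrics$rmse, rep(0, 6), tolerance = 1e-9)
  expect_equal(val$metrics$n_outliers_removed, rep(0L, 6))
  expect_equal(max(val$points$diff), 0, tolerance = 1e-9)
  # metrics unchanged when model and measurement translate together
  sh <- rigid_transform(t = c(30, -20, 10))
  mesh2 <- ph$mesh
  mesh2$nodes <- transform_points(sh, mesh2$nodes)
  cl2 <- lapply(cl, apply_transform, transform = sh)
  val2 <- validate_displacements(mesh2, ph$solution, cl2,
                                 list("RoI_L2", "RoI_L3"),
                                 validation_config(radius = 0.5))
  expect_equal(val2$metrics$r_squared, val$metrics$r_squared,
               tolerance = 1e-9)
  expect_equal(val2$metrics$rmse, val$metrics$rmse, tolerance = 1e-9)
  # report writers
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_validation_report(val, csv, js)
  wide <- readr::read_csv(csv, show_col_types = FALSE)
  expect_true("RoI_L2_SI" %in% names(wide))
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
  expect_s3_class(tidy(val), "tbl_df")
  expect_equal(glance(val)$min_r_squared, 1, tolerance = 1e-9)
  expect_s3_class(autoplot(val), "ggplot")
})
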