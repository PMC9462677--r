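# synthetic specimen generator: determinism, density structure,
# marker frames and DIC-like noise

test_that("phantom generation is deterministic and self-consistent", {
  a <- make_phantom(phantom_spec(edge = 8), solve = FALSE)
  b <- make_phantom(phantom_spec(edge = 8), solve = FALSE)
  expect_identical(a$mesh$nodes, b$mesh$nodes)
  expect_identical(a$mesh$elements, b$mesh$elements)
  expect_identical(a$grid$values, b$grid$values)
  expect_identical(a$markers, b$markers)
  # pilot point is the top marker-cluster centroid
  top0 <- a$markers[a$markers$pot == "top" & a$markers$frame == 0, ]
  expect_equal(a$pilot, pilot_point(as.matrix(top0[, c("x", "y", "z")])))
  # RoI node sets exist on the free lateral surface
  expect_gt(length(a$mesh$node_sets$RoI_L2), 20)
  expect_gt(length(a$mesh$node_sets$RoI_L3), 20)
})

test_that("the lesion lowers the mapped modulus and L3 is osteoporotic", {
  ph <- coarse_phantom_fix()
  mesh <- ph$mesh
  spec <- ph$spec
  # element centroids
  cen <- (mesh$nodes[mesh$elements[, 1], ] +
            mesh$nodes[mesh$elements[, 2], ] +
            mesh$nodes[mesh$elements[, 3], ] +
            mesh$nodes[mesh$elements[, 4], ]) / 4
  l2 <- mesh$element_sets$bone_L2
  zb <- attr(mesh, "region_bounds")
  l2mid <- (zb[5] + zb[6]) / 2
  ell <- ((cen[l2, 1] - spec$lesion_center[1]) / spec$lesion_semiaxes[1])^2 +
    ((cen[l2, 2] - spec$lesion_center[2]) / spec$lesion_semiaxes[2])^2 +
    ((cen[l2, 3] - l2mid - spec$lesion_center[3]) /
       spec$lesion_semiaxes[3])^2
  inside <- l2[ell < 0.5]; outside <- l2[ell > 1.5]
  expect_gt(length(inside), 0)
  # direct evaluation of the density chain on both regions
  E_lesion <- rho_qct_to_modulus(spec$lesion_vbmd)$E
  E_bg <- rho_qct_to_modulus(spec$background_vbmd)$E
  expect_lt(mean(mesh$E[inside]), mean(mesh$E[outside]))
  expect_equal(mean(mesh$E[inside]), E_lesion, tolerance = 0.15)
  expect_equal(mean(mesh$E[outside]), E_bg, tolerance = 0.15)
  # osteoporotic L3 sits below the healthy background
  E_l3 <- mean(mesh$E[mesh$element_sets$bone_L3])
  expect_equal(E_l3, rho_qct_to_modulus(spec$osteoporotic_vbmd)$E,
               tolerance = 0.15)
  expect_lt(E_l3, mean(mesh$E[outside]))
})

test_that("marker frames reproduce the pot motion they encode", {
  spec <- phantom_spec()
  # zero motion: deformed equals reference
  mk0 <- synth_marker_frames(rigid_transform(), spec)
  expect_equal(mk0[mk0$frame == 1, c("x", "y", "z")],
               mk0[mk0$frame == 0, c("x", "y", "z")],
               ignore_attr = TRUE)
  # published motion: recovered by the extractor (noise-free)
  motion <- spinefe:::pot_motion_published(about = c(10, -5, 120))
  mk <- synth_marker_frames(motion, spec)
  rec <- marker_motion(mk)
  probe <- matrix(c(25, 10, 100), 1)
  expect_equal(transform_points(rec, probe),
               transform_points(motion, probe), tolerance = 1e-9)
  # marker noise breaks exact recovery monotonically
  mkn <- synth_marker_frames(motion, spec, noise_sd = 0.01, seed = 3)
  refn <- as.matrix(mkn[mkn$frame == 0, c("x", "y", "z")])
  defn <- as.matrix(mkn[mkn$frame == 1, c("x", "y", "z")])
  recn <- extract_rigid_motion(refn, defn)
  expect_gt(recn$rms, 0)
  expect_lt(marker_motion(mk)$rms, 1e-12)
})

test_that("DIC noise injection matches the declared error model", {
  ph <- coarse_phantom_fix()
  spec <- ph$spec
  roi <- ph$mesh$node_sets$RoI_L2
  truth <- ph$solution$U[roi, ]
  errs <- lapply(1:20, function(s)
    synth_dic_cloud(ph$solution, ph$mesh, "RoI_L2", spec,
                    seed = s)$displacements - truth)
  all_err <- do.call(rbind, errs)
  # random part: per-component sd about 25 um
  centered <- sweep(all_err, 2, colMeans(all_err))
  expect_equal(apply(centered, 2, stats::sd),
               rep(spec$dic_noise_random, 3), tolerance = 0.05)
  # systematic part: constant offset of magnitude about 10 um
  expect_equal(sqrt(sum(colMeans(all_err)^2)),
               spec$dic_noise_systematic, tolerance = 0.1)
  # zero-noise clouds reproduce the solution exactly
  clean <- synth_dic_cloud(ph$solution, ph$mesh, "RoI_L2", spec,
                           noise = FALSE)
  expect_identical(clean$displacements, truth)
  # same seed, same cloud
  c1 <- synth_dic_cloud(ph$solution, ph$mesh, "RoI_L2", spec, seed = 9)
  c2 <- synth_dic_cloud(ph$solution, ph$mesh, "RoI_L2", spec, seed = 9)
  expect_identical(c1$displacements, c2$displacements)
})

test_that("the anterior surface of L3 is in flexion-dominated compression", {
  ph <- phantom_fix()
  s_ant <- mean_axial_strain(ph$mesh, ph$solution, "RoI_L3")
  expect_lt(s_ant, 0)
  # posterior band for comparison: flexion loads the anterior side more
  mesh <- ph$mesh
  ang <- atan2(mesh$nodes[, 1], mesh$nodes[, 2])
  rad <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  zb <- attr(mesh, "region_bounds")
  surf <- mesh_surface(mesh)
  post <- intersect(surf$nodes, which(
    mesh$nodes[, 3] > zb[3] + 2 & mesh$nodes[, 3] < zb[4] - 2 &
      abs(abs(ang) - pi) < 75 * pi / 180 & rad > 0.9 * ph$spec$radius))
  s_post <- mean_axial_strain(mesh, ph$solution, post)
  expect_lt(s_ant, s_post)
})

test_that("a mis-registered cloud is recovered by the registration stage", {
  ph <- phantom_fix()
  mis <- rigid_transform(rotation_axis_angle(c(0.3, 1, 0.2),
                                             1.5 * pi / 180),
                         t = c(0.4, -0.3, 0.5), about = c(0, 0, 50))
  cl <- synth_dic_cloud(ph$solution, ph$mesh, "RoI_L2", ph$spec,
                        noise = FALSE, misregistration = mis)
  reg <- register_rigid(cl, ph$mesh)
  back <- apply_transform(cl, reg$transform)
  orig <- ph$mesh$nodes[ph$mesh$node_sets$RoI_L2, ]
  expect_lt(max(abs(back$points - orig)), 1e-3)
  expect_lt(max(abs(back$displacements -
                      ph$solution$U[ph$mesh$node_sets$RoI_L2, ])), 1e-3)
})
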