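test_that("sampled parameters respect the morphological ranges and validity", {
  rng <- default_param_ranges()
  for (ty in c("type1", "type2")) {
    draws <- lapply(seq_len(5000), function(i) sample_params(ty, seed = i))
    for (nm in c("DA", "CC", "DP")) {
      v <- vapply(draws, `[[`, 0, nm)
      expect_true(all(v >= rng[[nm]][1] & v <= rng[[nm]][2]))
    }
    CC <- vapply(draws, `[[`, 0, "CC")
    DA <- vapply(draws, `[[`, 0, "DA")
    DP <- vapply(draws, `[[`, 0, "DP")
    expect_true(all(CC < (DA + DP) / 2))
    expect_true(all(CC + DA / 2 > DP / 2))
    CP <- vapply(draws, `[[`, 0, "CP")
    if (ty == "type1") {
      expect_true(all(CP == 0))
    } else {
      expect_true(all(CP >= rng$CP[1] & CP <= rng$CP[2]))
      LA <- vapply(draws, `[[`, 0, "LA")
      expect_true(all(LA >= 0 & LA <= 180))
    }
  }
})

test_that("parameter sampling is seed-deterministic", {
  expect_identical(sample_params("type2", seed = 3), sample_params("type2", seed = 3))
  expect_false(identical(sample_params("type2", seed = 3),
                         sample_params("type2", seed = 4)))
})

test_that("degenerate parameter combinations are rejected", {
  expect_error(aneurysm_params("type2", DA = 8, CC = 12, DP = 8, CP = 0.02),
               "degenerate")
  expect_error(aneurysm_params("type1", DA = 10, CC = 7, DP = 10, CP = 0.02),
               "CP = 0")
})

test_that("centerline has the prescribed curvature and arc geometry", {
  p <- aneurysm_params("type2", DA = 10, CC = 7, DP = 10, CP = 0.02, LA = 45)
  cl <- build_centerline(p)
  # osculating radius 1/CP = 50 mm at every station
  s <- seq(0, cl$L, length.out = 20)
  fr <- centerline_frame(cl, s)
  expect_equal(cl$R, 0.05)
  expect_true(all(abs(sqrt(rowSums(fr$tangent^2)) - 1) < 1e-12))
  # numerical curvature from second differences
  h <- 1e-4
  f0 <- centerline_frame(cl, 0.05)$point
  fp <- centerline_frame(cl, 0.05 + h)$point
  fm <- centerline_frame(cl, 0.05 - h)$point
  kappa <- sqrt(sum(((fp - 2 * f0 + fm) / h^2)^2))
  expect_equal(kappa, 20, tolerance = 1e-4)          # CP in 1/m
  # chord shorter than arc for a curved centerline
  chord <- sqrt(sum((centerline_frame(cl, cl$L)$point -
                       centerline_frame(cl, 0)$point)^2))
  expect_lt(chord, cl$L)
  # straight limit: zero curvature, chord equals arc
  p1 <- aneurysm_params("type1", DA = 10, CC = 7, DP = 10)
  cl1 <- build_centerline(p1)
  expect_identical(cl1$k, 0)
  expect_equal(sqrt(sum((centerline_frame(cl1, cl1$L)$point)^2)), cl1$L)
  # at least 10 DP of artery upstream of the sac
  expect_gte(cl$s_sac, 10 * p$DP * 1e-3 - 1e-12)
})

test_that("solid classification: sac center, upstream lumen, outside points", {
  g <- fix_geom_type2()
  expect_lt(signed_distance(g, rbind(g$sac_center)), 0)
  expect_identical(point_region(g, rbind(g$sac_center)), "aneurysm_sac")
  up <- centerline_frame(g$centerline, 0.2 * g$centerline$s_sac)$point
  expect_lt(signed_distance(g, up), 0)
  expect_identical(point_region(g, up), "parent_artery")
  far <- up + c(0, 0, 10 * g$r_tube)
  expect_gt(signed_distance(g, far), 0)
  expect_identical(point_region(g, far), "outside")
})

test_that("region labels agree with brute-force nearest-body classification", {
  g <- fix_geom_type2(seed = 11)
  pts <- sample_interior_points(g, 0.02, seed = 5)
  reg <- point_region(g, pts)
  expect_true(all(reg %in% c("parent_artery", "aneurysm_sac")))
  # brute force: inside tube (distance to densely sampled centerline < r)
  s_dense <- seq(0, g$centerline$L, length.out = 4000)
  cl_pts <- centerline_frame(g$centerline, s_dense)$point
  d_tube <- apply(pts, 1, function(p)
    min(sqrt(colSums((t(cl_pts) - p)^2))))
  in_tube <- d_tube < g$r_tube + 1e-6
  in_sph <- sqrt(rowSums(sweep(pts, 2, g$sac_center)^2)) < g$r_sac
  expect_true(all((reg == "aneurysm_sac") == (in_sph & !in_tube)))
})

test_that("neck patch is non-empty with positive area for an overlapping draw", {
  p <- aneurysm_params("type2", DA = 10, CC = 7, DP = 10, CP = 0.02, LA = 90)
  g <- build_geometry(p)
  np <- neck_patch(g, n = 8000, seed = 2)
  expect_gt(nrow(np$points), 0)
  expect_gt(np$area, 0)
  # brute-force oracle: patch points satisfy both surface equations
  wall_dev <- abs(hemocloud:::tube_coords(g, np$points)$d_curve - g$r_tube)
  expect_lt(max(wall_dev), 1e-9)
  expect_true(all(sqrt(rowSums(sweep(np$points, 2, g$sac_center)^2)) < g$r_sac))
})

test_that("surface samples lie on the boundary and scale with density", {
  g <- fix_geom_type2()
  sp <- sample_surface_points(g, 0.05, seed = 9)
  expect_lt(max(abs(signed_distance(g, sp))), 1e-9)
  n1 <- nrow(sample_surface_points(g, 0.02, seed = 1))
  n4 <- nrow(sample_surface_points(g, 0.08, seed = 1))
  expect_gt(n4 / n1, 4 * 0.8)
  expect_lt(n4 / n1, 4 * 1.2)
  expect_identical(sample_surface_points(g, 0.05, seed = 9), sp)
})

test_that("interior samples are strictly inside; sac can be masked off", {
  g <- fix_geom_type2()
  ip <- sample_interior_points(g, 0.03, seed = 4)
  expect_true(all(signed_distance(g, ip) < 0))
  expect_identical(sample_interior_points(g, 0.03, seed = 4), ip)
  no_sac <- sample_interior_points(g, 0.03, seed = 4, include_sac = FALSE)
  expect_false(any(point_region(g, no_sac) == "aneurysm_sac"))
})

test_that("porous-layer query points sit in the 150 um neck shell", {
  g <- fix_geom_type2()
  lp <- sample_layer_points(g, 12, seed = 6)
  expect_gt(nrow(lp), 0)
  tc <- hemocloud:::tube_coords(g, lp)
  expect_true(all(tc$d_curve > g$r_tube))
  expect_true(all(tc$d_curve < g$r_tube + 150e-6 + 1e-9))
  expect_true(all(point_region(g, lp) == "aneurysm_sac"))
})

test_that("curved geometry converges to the straight geometry as CP -> 0", {
  base <- list(DA = 10, CC = 7, DP = 10)
  g1 <- build_geometry(aneurysm_params("type1", base$DA, base$CC, base$DP))
  pts <- sample_interior_points(g1, 0.02, seed = 8)
  prev <- Inf
  for (cp in c(1e-3, 1e-5, 1e-7)) {
    g2 <- build_geometry(aneurysm_params("type2", base$DA, base$CC, base$DP,
                                         CP = cp, LA = 90))
    dev <- max(abs(signed_distance(g2, pts) - signed_distance(g1, pts)))
    expect_lt(dev, prev)
    prev <- dev
  }
  # lateral deflection of the centerline scales as L^2 k / 2, so the
  # signed-distance deviation decays linearly with CP
  expect_lt(prev, 5e-6)
})
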