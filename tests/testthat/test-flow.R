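test_that("Poiseuille profile has the closed-form mean and centerline speed", {
  # DP = 10 mm, defaults: v_mean = 0.004375/(1050*pi*0.005^2) = 0.05305 m/s
  R <- 0.005
  v_mean <- 0.004375 / (1050 * pi * R^2)
  expect_equal(v_mean, 0.05305, tolerance = 1e-4)
  expect_equal(poiseuille_profile(0, R), 2 * v_mean, tolerance = 1e-12)
  expect_equal(poiseuille_profile(0, R), 0.1061, tolerance = 1e-3)
  expect_identical(poiseuille_profile(R, R), 0)
  expect_error(poiseuille_profile(1.01 * R, R), "outside the lumen")
  # quadrature of rho*v over the disc recovers the inlet mass flow
  n <- 400
  r_mid <- (seq_len(n) - 0.5) * R / n
  flux <- sum(1050 * poiseuille_profile(r_mid, R) * 2 * pi * r_mid * R / n)
  expect_equal(flux, 0.004375, tolerance = 1e-3)
})

test_that("curved profile reduces to Poiseuille at CP = 0 and skews outward", {
  R <- 0.005
  r <- runif(50, 0, R); psi <- runif(50, -pi, pi)
  straight <- curved_profile(r, psi, R, CP = 0)
  expect_equal(straight$axial, poiseuille_profile(r, R), tolerance = 1e-14)
  expect_true(all(straight$u_r == 0) && all(straight$u_psi == 0))
  # CP = 0.033: outer-wall half carries > 50% of the axial flux
  n_r <- 120; n_psi <- 180
  gr <- expand.grid(r = (seq_len(n_r) - 0.5) * R / n_r,
                    psi = (seq_len(n_psi) - 0.5) * 2 * pi / n_psi - pi)
  cp <- curved_profile(gr$r, gr$psi, R, CP = 0.033)
  dA <- gr$r * (R / n_r) * (2 * pi / n_psi)
  flux <- cp$axial * dA
  outer <- cos(gr$psi) > 0
  expect_gt(sum(flux[outer]) / sum(flux), 0.5)
  # skew integrates out: total flux equals the straight-tube flux
  expect_equal(sum(flux), sum(poiseuille_profile(gr$r, R) * dA),
               tolerance = 5e-3)
})

test_that("mass flux is conserved along straight and curved arteries", {
  for (ty in c("type1", "type2")) {
    g <- build_geometry(sample_params(ty, seed = 5))
    target <- 0.004375
    for (s_frac in c(0.02, 0.4, 0.75)) {
      mf <- section_mass_flux(g, s = s_frac * g$centerline$L)
      expect_equal(mf, target, tolerance = 0.01)
    }
  }
})

test_that("sac field is a single vortex fed at the distal neck", {
  g <- fix_geom_type2()
  pts <- sample_interior_points(g, 0.05, seed = 2)
  sac <- point_region(g, pts) == "aneurysm_sac"
  sf <- sac_field(g, pts[sac, , drop = FALSE], neck_inflow = 0.03)
  expect_true(all(is.finite(sf$V)))
  # zero inflow -> identically zero field
  sf0 <- sac_field(g, pts[sac, , drop = FALSE], neck_inflow = 0)
  expect_true(all(sf0$V == 0))
  # peak speed proportional to the inflow
  sf2 <- sac_field(g, pts[sac, , drop = FALSE], neck_inflow = 0.06)
  expect_equal(sf2$V, 2 * sf$V, tolerance = 1e-12)
  # discrete circulation around the vortex axis has a consistent sign on
  # the sac equatorial plane
  tv <- g$sac_frame$tangent; nv <- g$sac_frame$normal
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- t(vapply(theta, function(a)
    g$sac_center + 0.5 * g$r_sac * (cos(a) * tv + sin(a) * nv), numeric(3)))
  vr <- sac_field(g, ring, neck_inflow = 0.03)$V
  e_t <- t(vapply(theta, function(a) -sin(a) * tv + cos(a) * nv, numeric(3)))
  circ <- rowSums(vr * e_t)
  expect_true(all(circ > 0) || all(circ < 0))
  expect_error(sac_field(g, ring, 0.03, "postop"), "porous_layer")
})

test_that("post-operative sac speeds drop below pre-operative pointwise", {
  g <- fix_geom_type2()
  qc <- sample_interior_points(g, 0.04, seed = 3)
  pre <- generate_flow(g, qc, operative_state = "preop", seed = 11)
  post <- generate_flow(g, qc, operative_state = "postop",
                        layer = porous_layer(), seed = 11)
  sac <- pre$region == "aneurysm_sac"
  expect_gt(sum(sac), 10)
  sp_pre <- sqrt(rowSums(pre$V[sac, ]^2))
  sp_post <- sqrt(rowSums(post$V[sac, ]^2))
  expect_true(all(sp_post <= sp_pre + 1e-15))
  expect_lt(mean(sp_post), mean(sp_pre))
})

test_that("shunt holds across 50 seeded geometries and strengthens with C", {
  ratios <- numeric(0)
  for (i in 1:50) {
    ty <- if (i %% 5 == 0) "type1" else "type2"
    g <- build_geometry(sample_params(ty, seed = 1000 + i))
    qc <- sample_interior_points(g, 0.01, seed = i)
    sac_pts <- qc[point_region(g, qc) == "aneurysm_sac", , drop = FALSE]
    if (nrow(sac_pts) < 3) next
    u <- neck_inflow_speed(g)
    pre <- sac_field(g, sac_pts, u, "preop")
    post <- sac_field(g, sac_pts, u, "postop", porous_layer())
    m_pre <- mean(sqrt(rowSums(pre$V^2)))
    m_post <- mean(sqrt(rowSums(post$V^2)))
    expect_lt(m_post, m_pre)
    stiff <- sac_field(g, sac_pts, u, "postop", porous_layer(C = 4 * 7665))
    expect_lt(mean(sqrt(rowSums(stiff$V^2))), m_post)
    ratios <- c(ratios, m_post / m_pre)
  }
  expect_gt(length(ratios), 40)
  expect_true(all(ratios < 1))
})

test_that("pressure anchors at the outlet and follows Hagen-Poiseuille", {
  # straight tube, DP = 10 mm, length 0.1 m: end-to-end drop
  # 8 mu v_mean L / R^2 = 0.594 Pa
  p <- aneurysm_params("type1", DA = 10, CC = 7, DP = 10)
  g <- build_geometry(p)
  g$centerline$L <- 0.1
  g$centerline$s_sac <- 0.05
  outlet <- centerline_frame(g$centerline, g$centerline$L)$point
  inlet <- centerline_frame(g$centerline, 0)$point
  pr <- pressure_solution(g, rbind(outlet, inlet),
                          region = c("parent_artery", "parent_artery"))
  expect_equal(pr[1], 0, tolerance = 1e-6)
  v_mean <- 0.004375 / (1050 * pi * 0.005^2)
  expect_equal(pr[2] - pr[1], 8 * 0.0035 * v_mean * 0.1 / 0.005^2,
               tolerance = 1e-12)
  expect_equal(pr[2] - pr[1], 5.94, tolerance = 1e-3)
})

test_that("post-operative sac pressure offset equals the layer pressure drop", {
  g <- fix_geom_type2()
  qc <- sample_interior_points(g, 0.04, seed = 3)
  reg <- point_region(g, qc)
  sac <- reg == "aneurysm_sac"
  layer <- porous_layer()
  p_pre <- pressure_solution(g, qc, reg, "preop")
  p_post <- pressure_solution(g, qc, reg, "postop", layer)
  u_pre <- neck_inflow_speed(g)
  u_eff <- u_pre * transmission_factor(u_pre, 0.5 * 1050 * u_pre^2,
                                       layer = layer)
  offs <- p_pre[sac] - p_post[sac]
  expect_equal(max(abs(offs - pressure_drop(u_eff, layer = layer))), 0,
               tolerance = 1e-12)
  expect_true(all(p_pre[!sac] == p_post[!sac]))
})

test_that("generated fields are seeded, bounded-noise compositions", {
  g <- fix_geom_type2()
  qc <- sample_interior_points(g, 0.03, seed = 6)
  f1 <- generate_flow(g, qc, seed = 21)
  f2 <- generate_flow(g, qc, seed = 21)
  expect_identical(f1$V, f2$V)
  expect_identical(f1$P, f2$P)
  f3 <- generate_flow(g, qc, seed = 22)
  expect_false(identical(f1$V, f3$V))
  # zero noise equals the analytic composition; noise stays within bound
  f0 <- generate_flow(g, qc, noise_fraction = 0, seed = 21)
  speed0 <- sqrt(rowSums(f0$V^2))
  dv <- sqrt(rowSums((f1$V - f0$V)^2))
  expect_true(all(dv <= sqrt(3) * 0.02 * speed0 + 1e-15))
  # points outside the solid are rejected with indices
  bad <- rbind(qc[1, ] + c(0, 0, 1))
  expect_error(generate_flow(g, rbind(qc, bad)), "outside the solid")
})

test_that("no-slip: wall-adjacent query points are slow", {
  for (ty in c("type1", "type2")) {
    g <- build_geometry(sample_params(ty, seed = 17))
    qc <- sample_interior_points(g, 0.03, seed = 8)
    ff <- generate_flow(g, qc, seed = 2)
    wall_dist <- -signed_distance(g, qc)
    near <- wall_dist < 0.02 * g$r_tube
    expect_gt(sum(near), 5)
    v_mean <- ff$meta$v_mean
    expect_true(all(sqrt(rowSums(ff$V[near, , drop = FALSE]^2)) < 0.1 * v_mean))
  }
})

test_that("type-2 flow converges to the type-1 flow as CP -> 0", {
  base <- aneurysm_params("type1", DA = 10, CC = 7, DP = 10)
  g1 <- build_geometry(base)
  qc <- sample_interior_points(g1, 0.02, seed = 12)
  f1 <- generate_flow(g1, qc, noise_fraction = 0)
  prev <- Inf
  for (cp in c(1e-3, 1e-5, 1e-7)) {
    g2 <- build_geometry(aneurysm_params("type2", 10, 7, 10, CP = cp, LA = 90))
    inside <- signed_distance(g2, qc) < -1e-9    # common interior
    f2 <- generate_flow(g2, qc[inside, , drop = FALSE], noise_fraction = 0)
    dev <- max(abs(f2$V - f1$V[inside, , drop = FALSE]))
    expect_lt(dev, prev)
    prev <- dev
  }
  expect_lt(prev, 1e-4)
})
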