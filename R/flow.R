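#' Inlet boundary conditions
#'
#' @param inlet_mass_flow inlet mass flow, kg/s (default 0.004375).
#' @param outlet_pressure outlet static pressure, Pa (default 0).
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_mass_flow = 0.004375, outlet_pressure = 0) {
  stopifnot(inlet_mass_flow > 0)
  structure(list(inlet_mass_flow = inlet_mass_flow,
                 outlet_pressure = outlet_pressure),
            class = "boundary_conditions")
}

mean_speed <- function(bc, props, R) {
  bc$inlet_mass_flow / (props$rho * pi * R^2)
}

#' Poiseuille axial velocity profile
#'
#' Fully developed laminar profile `v(r) = 2 v_mean (1 - (r/R)^2)` with
#' `v_mean = mdot / (rho pi R^2)`; zero at the wall (no slip).
#'
#' @param r radial position, m (vectorized).
#' @param R tube radius, m.
#' @param bc a `boundary_conditions`.
#' @param props a `fluid_props`.
#' @return axial speed, m/s.
#' @export
poiseuille_profile <- function(r, R, bc = boundary_conditions(),
                               props = fluid_props()) {
  if (any(r < 0) || any(r > R * (1 + 1e-12)))
    stop("poiseuille_profile: radial position outside the lumen")
  2 * mean_speed(bc, props, R) * (1 - (r / R)^2)
}

# Skew of the axial profile toward the outer wall and the Dean-like
# amplitude of the in-plane secondary circulation, both dimensionless
# functions of the tube geometry. DP in mm, CP in 1/mm. The skew cap keeps
# the near-wall decay contract (< 10% of v_mean within 2% of the wall)
# satisfiable at the strongest curvature.
curvature_skew <- function(DP, CP) min(0.2, 1.2 * DP * CP)

secondary_amplitude <- function(DP, CP, bc, props) {
  R <- DP / 2 * 1e-3
  re <- props$rho * mean_speed(bc, props, R) * (2 * R) / props$mu
  min(0.35, 0.8 * sqrt(pmax(0, DP / 2 * CP)) * re / 160)
}

#' In-section velocity field of a curved artery
#'
#' Axial profile skewed toward the outer wall,
#' `v_ax = 2 v_mean (1 - rho^2) (1 + delta rho cos(psi))` with `rho = r/R`
#' and `psi = 0` at the outer wall, plus a weak two-cell in-plane secondary
#' circulation with Dean-like amplitude. The skew term integrates to zero
#' over the section, so the mass flow is that of the straight profile
#' exactly; with `CP = 0` the field reduces to [poiseuille_profile()].
#'
#' @param r radial positions, m.
#' @param psi in-section azimuth, radians, 0 at the outer wall.
#' @param R tube radius, m.
#' @param CP centerline curvature, 1/mm.
#' @inheritParams poiseuille_profile
#' @return list with `axial` (m/s) and in-plane components `u_r`, `u_psi`.
#' @export
curved_profile <- function(r, psi, R, CP, bc = boundary_conditions(),
                           props = fluid_props()) {
  stopifnot(CP >= 0)
  DP <- 2 * R * 1e3
  rho <- clamp(r / R, 0, 1)
  vm <- mean_speed(bc, props, R)
  delta <- if (CP > 0) curvature_skew(DP, CP) else 0
  eps <- if (CP > 0) secondary_amplitude(DP, CP, bc, props) else 0
  axial <- 2 * vm * (1 - rho^2) * (1 + delta * rho * cos(psi))
  # two-cell circulation from the stream function
  # Phi = eps vm R rho^2 (1-rho^2)^2 sin(psi)
  u_r <- eps * vm * rho * (1 - rho^2)^2 * cos(psi)
  u_psi <- -eps * vm * (2 * rho * (1 - rho^2)^2 - 4 * rho^3 * (1 - rho^2)) * sin(psi)
  list(axial = axial, u_r = u_r, u_psi = u_psi)
}

#' Characteristic neck inflow speed of a geometry
#'
#' Speed scale of the jet entering the sac through the neck orifice before
#' any stent is placed. Modelled from observable geometry only: the parent
#' mean speed, a curvature enhancement `(1 + DP*CP)` (stronger near-wall
#' momentum on the outer bend) and an orifice-size factor
#' `(0.5 + 0.5 w/r_sac)`.
#'
#' @param geom an `aneurysm_geometry`.
#' @inheritParams poiseuille_profile
#' @return speed, m/s.
#' @export
neck_inflow_speed <- function(geom, bc = boundary_conditions(),
                              props = fluid_props()) {
  vm <- mean_speed(bc, props, geom$r_tube)
  0.55 * vm * (1 + geom$params$DP * geom$params$CP) *
    (0.5 + 0.5 * min(1, geom$w_neck / geom$r_sac))
}

#' Recirculating velocity field inside the aneurysm sac
#'
#' A single vortex: the inflow jet enters at the distal edge of the neck,
#' circulates along the sac wall and decays to a near-zero core and to zero
#' at the wall. Peak speed is proportional to `neck_inflow`; in the
#' post-operative state the inflow is first attenuated by the porous-layer
#' [transmission_factor()] driven by the stagnation pressure of the jet.
#'
#' @param geom an `aneurysm_geometry`.
#' @param pts n x 3 sac points, m.
#' @param neck_inflow approach speed at the neck, m/s (>= 0).
#' @param operative_state `"preop"` or `"postop"`.
#' @param layer `porous_layer`, required for `"postop"`.
#' @param props a `fluid_props`.
#' @return list with `V` (n x 3 velocity, m/s) and `u_eff` (effective
#'   post-attenuation inflow speed).
#' @export
sac_field <- function(geom, pts, neck_inflow,
                      operative_state = c("preop", "postop"),
                      layer = NULL, props = fluid_props()) {
  operative_state <- match.arg(operative_state)
  stopifnot(neck_inflow >= 0)
  u <- neck_inflow
  if (operative_state == "postop") {
    if (is.null(layer))
      stop("sac_field: postop state requires a porous_layer")
    if (u > 0) {
      dp <- 0.5 * props$rho * u^2
      u <- u * transmission_factor(u, dp, props, layer)
    }
  }
  pts <- rbind(pts)
  if (u == 0 || nrow(pts) == 0)
    return(list(V = matrix(0, nrow(pts), 3), u_eff = u))
  tv <- geom$sac_frame$tangent
  nv <- geom$sac_frame$normal
  bv <- c(tv[2] * nv[3] - tv[3] * nv[2],
          tv[3] * nv[1] - tv[1] * nv[3],
          tv[1] * nv[2] - tv[2] * nv[1])       # vortex axis t x n
  omega <- 2.4 * u / geom$r_sac
  d <- sweep(pts, 2, geom$sac_center)
  rho <- clamp(vec_norm(d) / geom$r_sac, 0, 1)
  cx <- cbind(bv[2] * d[, 3] - bv[3] * d[, 2],
              bv[3] * d[, 1] - bv[1] * d[, 3],
              bv[1] * d[, 2] - bv[2] * d[, 1])
  list(V = omega * cx * (1 - rho^2), u_eff = u)
}

#' Per-point pressure field
#'
#' Hagen-Poiseuille axial gradient `dP/ds = 8 mu v_mean / R^2` along the
#' artery, anchored to the outlet pressure at the outlet; the sac is held at
#' the neck-station pressure plus a stagnation-scale dip toward the sac
#' core. Post-operatively the whole sac is additionally offset by the
#' porous-layer [pressure_drop()] at the transmitted neck speed.
#'
#' @param geom an `aneurysm_geometry`.
#' @param pts n x 3 points, m.
#' @param region character region labels for `pts` (from [point_region()]).
#' @inheritParams sac_field
#' @param bc a `boundary_conditions`.
#' @return pressure, Pa.
#' @export
pressure_solution <- function(geom, pts, region,
                              operative_state = c("preop", "postop"),
                              layer = NULL,
                              bc = boundary_conditions(),
                              props = fluid_props()) {
  operative_state <- match.arg(operative_state)
  pts <- rbind(pts)
  cl <- geom$centerline
  vm <- mean_speed(bc, props, geom$r_tube)
  dpds <- 8 * props$mu * vm / geom$r_tube^2
  tc <- tube_coords(geom, pts)
  p <- bc$outlet_pressure + dpds * (cl$L - tc$s)
  sac <- region == "aneurysm_sac"
  if (any(sac)) {
    u_pre <- neck_inflow_speed(geom, bc, props)
    p_neck <- bc$outlet_pressure + dpds * (cl$L - cl$s_sac)
    rho <- clamp(vec_norm(sweep(pts[sac, , drop = FALSE], 2, geom$sac_center)) /
                   geom$r_sac, 0, 1)
    dip <- -0.3 * 0.5 * props$rho * u_pre^2 * (1 - rho^2)
    off <- 0
    if (operative_state == "postop") {
      if (is.null(layer))
        stop("pressure_solution: postop state requires a porous_layer")
      u_eff <- u_pre * transmission_factor(u_pre, 0.5 * props$rho * u_pre^2,
                                           props, layer)
      off <- -pressure_drop(u_eff, props, layer)
    }
    p[sac] <- p_neck + off + dip
  }
  p
}

# Smooth random scalar fields on a point set: sum of Gaussian bumps,
# normalized so each field has max |value| = 1 over the points.
smooth_noise_fields <- function(pts, n_fields, seed, n_bumps = 32L) {
  local_seed(seed, {
    n <- nrow(pts)
    if (n == 0) return(matrix(0, 0, n_fields))
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    diag_len <- sqrt(sum((hi - lo)^2))
    if (diag_len == 0) diag_len <- 1
    centers <- cbind(stats::runif(n_bumps, lo[1], hi[1]),
                     stats::runif(n_bumps, lo[2], hi[2]),
                     stats::runif(n_bumps, lo[3], hi[3]))
    w <- 0.15 * diag_len
    d2 <- outer(rowSums(pts^2), rep(1, n_bumps)) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * pts %*% t(centers)
    g <- exp(-pmax(d2, 0) / (2 * w^2))
    amp <- matrix(stats::rnorm(n_bumps * n_fields), n_bumps, n_fields)
    raw <- g %*% amp
    mx <- apply(abs(raw), 2, max)
    mx[mx == 0] <- 1
    sweep(raw, 2, mx, "/")
  })
}

#' Generate a steady flow field on query points
#'
#' Composes the parent-artery profile (parabolic, curvature-skewed with a
#' secondary in-plane circulation when curved), the sac vortex, and the
#' Hagen-Poiseuille pressure solution, then adds a smooth seeded
#' perturbation with amplitude at most `noise_fraction` of the local speed
#' (and of the local dynamic pressure for the pressure field). Fully
#' deterministic for a fixed seed.
#'
#' @param geom an `aneurysm_geometry`.
#' @param query n x 3 matrix of points inside the solid, m.
#' @param bc a `boundary_conditions`.
#' @param props a `fluid_props`.
#' @param operative_state `"preop"` or `"postop"`.
#' @param layer `porous_layer`, required for `"postop"`.
#' @param noise_fraction smooth perturbation amplitude as a fraction of the
#'   local speed (default 0.02).
#' @param seed RNG seed for the perturbation.
#' @param tol boundary tolerance for the inside check, m.
#' @return object of class `flow_field`: `points`, `V` (n x 3, m/s),
#'   `P` (n, Pa), `region`, `operative_state`, `meta`.
#' @export
generate_flow <- function(geom, query,
                          bc = boundary_conditions(),
                          props = fluid_props(),
                          operative_state = c("preop", "postop"),
                          layer = NULL,
                          noise_fraction = 0.02,
                          seed = NULL,
                          tol = 1e-7) {
  operative_state <- match.arg(operative_state)
  query <- rbind(query)
  sd <- signed_distance(geom, query)
  if (any(sd > tol)) {
    bad <- which(sd > tol)
    stop("generate_flow: ", length(bad), " query points outside the solid ",
         "(indices ", paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "", ")")
  }
  region <- point_region(geom, query)
  region[region == "outside"] <- "parent_artery"    # boundary-tolerance cases
  V <- matrix(0, nrow(query), 3)
  par <- region == "parent_artery"
  if (any(par)) {
    tc <- tube_coords(geom, query[par, , drop = FALSE])
    r <- pmin(tc$r, geom$r_tube)
    pr <- curved_profile(r, tc$psi, geom$r_tube, geom$params$CP, bc, props)
    b <- cbind(0, 0, 1)[rep(1, sum(par)), , drop = FALSE]
    e_r <- cos(tc$psi) * tc$normal + sin(tc$psi) * b
    e_psi <- -sin(tc$psi) * tc$normal + cos(tc$psi) * b
    V[par, ] <- pr$axial * tc$tangent + pr$u_r * e_r + pr$u_psi * e_psi
  }
  u_pre <- neck_inflow_speed(geom, bc, props)
  u_eff <- u_pre
  sac <- region == "aneurysm_sac"
  if (any(sac) || operative_state == "postop") {
    sf <- sac_field(geom, query[sac, , drop = FALSE], u_pre,
                    operative_state, layer, props)
    if (any(sac)) V[sac, ] <- sf$V
    u_eff <- sf$u_eff
  }
  P <- pressure_solution(geom, query, region, operative_state, layer, bc, props)
  if (noise_fraction > 0) {
    nf <- smooth_noise_fields(query, 4L, seed)
    speed <- vec_norm(V)
    V <- V + noise_fraction * speed * nf[, 1:3, drop = FALSE]
    P <- P + noise_fraction * 0.5 * props$rho * speed^2 * nf[, 4]
  }
  structure(list(
    points = query, V = V, P = P, region = region,
    operative_state = operative_state,
    meta = list(v_mean = mean_speed(bc, props, geom$r_tube),
                u_neck_pre = u_pre, u_neck_eff = u_eff,
                noise_fraction = noise_fraction, seed = seed,
                bc = bc, props = props)
  ), class = "flow_field")
}

#' Mass flux through an artery cross-section
#'
#' Midpoint polar quadrature of `rho * v_axial` over the section disc at
#' arc-length station `s`, evaluating a freshly generated surrogate field at
#' the quadrature nodes.
#'
#' @param geom an `aneurysm_geometry`.
#' @param s arc-length station of the section, m.
#' @param n_r,n_psi radial / azimuthal quadrature resolution.
#' @inheritParams generate_flow
#' @return mass flux, kg/s.
#' @export
section_mass_flux <- function(geom, s = 0.25 * geom$centerline$L,
                              n_r = 48, n_psi = 64,
                              bc = boundary_conditions(),
                              props = fluid_props(),
                              operative_state = "preop",
                              layer = NULL,
                              noise_fraction = 0, seed = NULL) {
  cl <- geom$centerline
  R <- geom$r_tube
  fr <- centerline_frame(cl, s)
  b <- c(0, 0, 1)
  r_mid <- (seq_len(n_r) - 0.5) * R / n_r
  psi_mid <- (seq_len(n_psi) - 0.5) * 2 * pi / n_psi
  gr <- expand.grid(r = r_mid, psi = psi_mid)
  pts <- matrix(fr$point[1, ], nrow(gr), 3, byrow = TRUE) +
    gr$r * (cos(gr$psi) * matrix(fr$normal[1, ], nrow(gr), 3, byrow = TRUE) +
              sin(gr$psi) * matrix(b, nrow(gr), 3, byrow = TRUE))
  ff <- generate_flow(geom, pts, bc, props, operative_state, layer,
                      noise_fraction, seed)
  v_ax <- as.numeric(ff$V %*% fr$tangent[1, ])
  dA <- gr$r * (R / n_r) * (2 * pi / n_psi)
  sum(props$rho * v_ax * dA)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "flow_field [%s]: %d points (%d sac), speed %.4f-%.4f m/s, P %.3f-%.3f Pa\n",
    x$operative_state, nrow(x$points), sum(x$region == "aneurysm_sac"),
    min(vec_norm(x$V)), max(vec_norm(x$V)), min(x$P), max(x$P)))
  invisible(x)
}
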