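#' Build a side-wall aneurysm solid
#'
#' The solid is the union of a tube of radius `DP/2` swept along the
#' parent-artery centerline and a sphere of radius `DA/2` whose center sits
#' at distance `CC` from the centerline at the sac station, offset along the
#' local outward normal (`sac_side = 1`, the outer wall of the bend) or the
#' inner wall (`sac_side = -1`). Everything is stored in SI meters.
#'
#' @param params an `aneurysm_params` object.
#' @param sac_side +1 (outer wall, default) or -1 (inner wall).
#' @param ... passed to [build_centerline()].
#' @return object of class `aneurysm_geometry`.
#' @export
build_geometry <- function(params, sac_side = 1, ...) {
  validate_params(params)
  cl <- build_centerline(params, ...)
  fr <- centerline_frame(cl, cl$s_sac)
  r_tube <- params$DP / 2 * 1e-3
  r_sac  <- params$DA / 2 * 1e-3
  cc     <- params$CC * 1e-3
  center <- fr$point[1, ] + sac_side * cc * fr$normal[1, ]
  # half-width of the neck orifice chord in the sac cross-plane
  h <- abs(cc - r_tube)
  w_neck <- if (h < r_sac) sqrt(r_sac^2 - h^2) else 0.1 * r_sac
  structure(list(
    params = params,
    centerline = cl,
    r_tube = r_tube,
    r_sac = r_sac,
    sac_center = center,
    sac_side = sac_side,
    sac_frame = list(point = fr$point[1, ], tangent = fr$tangent[1, ],
                     normal = sac_side * fr$normal[1, ]),
    w_neck = w_neck
  ), class = "aneurysm_geometry")
}

# Tube-fitted coordinates of arbitrary points: arc-length station s (clamped
# to [0, L]), distance to the centerline curve d_curve, in-section radius r,
# azimuth psi (0 at the outward normal), and axial unit tangent.
tube_coords <- function(geom, pts) {
  cl <- geom$centerline
  pts <- rbind(pts)
  if (nrow(pts) == 0) {
    z3 <- matrix(numeric(0), 0, 3)
    return(list(s = numeric(0), d_curve = numeric(0), r = numeric(0),
                psi = numeric(0), tangent = z3, normal = z3, point = z3))
  }
  if (cl$k == 0) {
    s_cl <- clamp(pts[, 1], 0, cl$L)
    r <- sqrt(pts[, 2]^2 + pts[, 3]^2)
    d_curve <- sqrt((pts[, 1] - s_cl)^2 + r^2)
    psi <- atan2(pts[, 3], pts[, 2])
    fr <- centerline_frame(cl, s_cl)
  } else {
    R <- cl$R
    th_tot <- cl$L * cl$k
    th_p <- atan2(pts[, 1], pts[, 2] + R)     # principal angle on the circle
    cand1 <- clamp(th_p, 0, th_tot)
    cand2 <- clamp(th_p + 2 * pi, 0, th_tot)
    p1 <- cbind(R * sin(cand1), R * cos(cand1) - R, 0)
    p2 <- cbind(R * sin(cand2), R * cos(cand2) - R, 0)
    d1 <- vec_norm(pts - p1)
    d2 <- vec_norm(pts - p2)
    use2 <- d2 < d1
    th <- ifelse(use2, cand2, cand1)
    d_curve <- pmin(d1, d2)
    s_cl <- th * R
    fr <- centerline_frame(cl, s_cl)
    rv <- pts - fr$point
    a_n <- rowSums(rv * fr$normal)
    a_b <- pts[, 3]
    r <- sqrt(a_n^2 + a_b^2)
    psi <- atan2(a_b, a_n)
  }
  if (cl$k == 0) {
    # recompute section components for the straight case (normal = +y)
    a_n <- pts[, 2]; a_b <- pts[, 3]
    psi <- atan2(a_b, a_n)
  }
  list(s = s_cl, d_curve = d_curve, r = r, psi = psi,
       tangent = fr$tangent, normal = fr$normal, point = fr$point)
}

#' Signed distance to the aneurysm solid
#'
#' Negative strictly inside, positive outside, ~0 on the boundary
#' (union of tube and sac sphere; the tube has rounded end caps).
#'
#' @param geom an `aneurysm_geometry`.
#' @param pts n x 3 matrix of points, m.
#' @return numeric vector of signed distances, m.
#' @export
signed_distance <- function(geom, pts) {
  pts <- rbind(pts)
  tc <- tube_coords(geom, pts)
  sd_tube <- tc$d_curve - geom$r_tube
  sd_sph <- vec_norm(sweep(pts, 2, geom$sac_center)) - geom$r_sac
  pmin(sd_tube, sd_sph)
}

#' Region label of points inside the solid
#'
#' A point belongs to the `aneurysm_sac` iff it lies inside the sac sphere
#' and outside the tube; points inside the tube (including the neck
#' interior, which is inside both bodies) are `parent_artery`; points
#' outside the solid are labelled `outside`.
#'
#' @inheritParams signed_distance
#' @param tol boundary tolerance, m.
#' @return character vector of labels.
#' @export
point_region <- function(geom, pts, tol = 1e-9) {
  pts <- rbind(pts)
  tc <- tube_coords(geom, pts)
  sd_tube <- tc$d_curve - geom$r_tube
  sd_sph <- vec_norm(sweep(pts, 2, geom$sac_center)) - geom$r_sac
  out <- rep("outside", nrow(pts))
  out[sd_tube < tol] <- "parent_artery"
  out[sd_sph < tol & sd_tube >= tol] <- "aneurysm_sac"
  out
}

#' Sample the neck patch
#'
#' The neck patch is the part of the artery wall surface that lies inside
#' the sac sphere -- the surface across which the flow-diverter porous layer
#' is laid. Returns sampled patch points, an area estimate, and the patch
#' center/normal.
#'
#' @param geom an `aneurysm_geometry`.
#' @param n number of wall-surface Monte-Carlo samples.
#' @param seed RNG seed.
#' @return list with `points` (k x 3), `area` (m^2), `center`, `normal`.
#' @export
neck_patch <- function(geom, n = 4000, seed = 1) {
  cl <- geom$centerline
  local_seed(seed, {
    # sample the wall near the sac station only: the sphere cannot reach
    # farther than r_sac along the tube
    s_lo <- max(0, cl$s_sac - 1.5 * geom$r_sac)
    s_hi <- min(cl$L, cl$s_sac + 1.5 * geom$r_sac)
    s <- stats::runif(n, s_lo, s_hi)
    phi <- stats::runif(n, 0, 2 * pi)
    fr <- centerline_frame(cl, s)
    b <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
    p <- fr$point + geom$r_tube * (cos(phi) * (geom$sac_side * fr$normal) + sin(phi) * b)
    inside <- vec_norm(sweep(p, 2, geom$sac_center)) < geom$r_sac
    area_sampled <- 2 * pi * geom$r_tube * (s_hi - s_lo)
    list(points = p[inside, , drop = FALSE],
         area = area_sampled * mean(inside),
         center = geom$sac_frame$point + geom$r_tube * geom$sac_frame$normal,
         normal = geom$sac_frame$normal)
  })
}

#' Sample points on the solid boundary
#'
#' Draws points on the lateral tube wall (excluding the part swallowed by
#' the sac) and on the sac sphere (excluding the part inside the tube), with
#' expected count `density` per mm^2 of surface.
#'
#' @param geom an `aneurysm_geometry`.
#' @param density points per mm^2.
#' @param seed RNG seed; fixed seed gives an identical point set.
#' @return n x 3 matrix of surface points, m.
#' @export
sample_surface_points <- function(geom, density, seed = NULL) {
  stopifnot(density > 0)
  cl <- geom$centerline
  local_seed(seed, {
    area_tube_mm2 <- 2 * pi * geom$r_tube * cl$L * 1e6
    area_sph_mm2 <- 4 * pi * geom$r_sac^2 * 1e6
    n_t <- round(density * area_tube_mm2)
    n_s <- round(density * area_sph_mm2)
    pt <- matrix(numeric(0), 0, 3)
    if (n_t >= 1) {
      s <- stats::runif(n_t, 0, cl$L)
      phi <- stats::runif(n_t, 0, 2 * pi)
      fr <- centerline_frame(cl, s)
      b <- matrix(c(0, 0, 1), n_t, 3, byrow = TRUE)
      pt <- fr$point + geom$r_tube * (cos(phi) * fr$normal + sin(phi) * b)
      pt <- pt[vec_norm(sweep(pt, 2, geom$sac_center)) >= geom$r_sac, ,
               drop = FALSE]
    }
    ps <- matrix(numeric(0), 0, 3)
    if (n_s >= 1) {
      dir <- matrix(stats::rnorm(3 * n_s), n_s, 3)
      dir <- dir / vec_norm(dir)
      ps <- sweep(geom$r_sac * dir, 2, geom$sac_center, "+")
      ps <- ps[tube_coords(geom, ps)$d_curve >= geom$r_tube, , drop = FALSE]
    }
    rbind(pt, ps)
  })
}

#' Sample points strictly inside the solid
#'
#' Volume sampling with near-wall refinement: the expected density is
#' doubled within `0.1 * DP` of the wall, emulating the boundary-refined
#' node distribution of a CFD mesh. Sac points lying inside the tube are
#' dropped (that region is covered by the tube sampler), so every sac-sphere
#' point carries the `aneurysm_sac` region label.
#'
#' @param geom an `aneurysm_geometry`.
#' @param density points per mm^3.
#' @param seed RNG seed.
#' @param include_sac if FALSE, only the parent-artery lumen is sampled.
#' @param refine near-wall density doubling on/off.
#' @return n x 3 matrix of interior points, m.
#' @export
sample_interior_points <- function(geom, density, seed = NULL,
                                   include_sac = TRUE, refine = TRUE) {
  stopifnot(density > 0)
  cl <- geom$centerline
  r_t <- geom$r_tube
  r_s <- geom$r_sac
  t_wall <- 0.1 * 2 * r_t             # refinement band: 0.1 * DP
  local_seed(seed, {
    sample_tube <- function(n, r_lo, r_hi) {
      if (n < 1) return(matrix(numeric(0), 0, 3))
      s <- stats::runif(n, 0, cl$L)
      rr <- sqrt(stats::runif(n, r_lo^2, r_hi^2))
      psi <- stats::runif(n, 0, 2 * pi)
      fr <- centerline_frame(cl, s)
      b <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
      fr$point + rr * (cos(psi) * fr$normal + sin(psi) * b)
    }
    vol_tube <- pi * r_t^2 * cl$L * 1e9                    # mm^3
    n_tube <- round(density * vol_tube)
    p_tube <- sample_tube(n_tube, 0, r_t * (1 - 1e-9))
    if (refine) {
      vol_shell <- pi * (r_t^2 - (r_t - t_wall)^2) * cl$L * 1e9
      p_tube <- rbind(p_tube,
                      sample_tube(round(density * vol_shell),
                                  r_t - t_wall, r_t * (1 - 1e-9)))
    }
    p <- p_tube
    if (include_sac) {
      sample_ball <- function(n, r_lo, r_hi) {
        if (n < 1) return(matrix(numeric(0), 0, 3))
        dir <- matrix(stats::rnorm(3 * n), n, 3)
        dir <- dir / vec_norm(dir)
        rr <- (stats::runif(n, r_lo^3, r_hi^3))^(1 / 3)
        sweep(rr * dir, 2, geom$sac_center, "+")
      }
      vol_sac <- 4 / 3 * pi * r_s^3 * 1e9
      ps <- sample_ball(round(density * vol_sac), 0, r_s * (1 - 1e-9))
      if (refine) {
        vol_shell <- 4 / 3 * pi * (r_s^3 - (r_s - t_wall)^3) * 1e9
        ps <- rbind(ps, sample_ball(round(density * vol_shell),
                                    r_s - t_wall, r_s * (1 - 1e-9)))
      }
      ps <- ps[tube_coords(geom, ps)$d_curve > r_t, , drop = FALSE]
      p <- rbind(p, ps)
    }
    p
  })
}

#' Sample query points inside the porous-layer shell at the neck
#'
#' Points within the 150 um layer volume just above the neck patch (inside
#' the sac sphere, just outside the artery wall). They carry no special
#' label: downstream stages treat them as ordinary sac-region query points.
#'
#' @param geom an `aneurysm_geometry`.
#' @param n number of points.
#' @param thickness layer thickness, m.
#' @param seed RNG seed.
#' @return k x 3 matrix (k <= n after clipping to the sphere).
#' @export
sample_layer_points <- function(geom, n, thickness = 150e-6, seed = NULL) {
  np <- neck_patch(geom, n = max(50L, 4L * n), seed = seed)
  if (nrow(np$points) == 0) return(matrix(numeric(0), 0, 3))
  local_seed(if (is.null(seed)) NULL else seed + 1L, {
    idx <- sample.int(nrow(np$points), min(n, nrow(np$points)))
    base <- np$points[idx, , drop = FALSE]
    tc <- tube_coords(geom, base)
    rad <- (base - tc$point) / tc$d_curve           # unit radial off the wall
    off <- stats::runif(nrow(base), 1e-7, thickness)
    p <- base + off * rad
    p[vec_norm(sweep(p, 2, geom$sac_center)) < geom$r_sac, , drop = FALSE]
  })
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  cat(sprintf(
    "aneurysm_geometry [%s]: tube r=%.2f mm L=%.1f mm, sac r=%.2f mm, neck half-width %.2f mm\n",
    x$params$model_type, x$r_tube * 1e3, x$centerline$L * 1e3, x$r_sac * 1e3,
    x$w_neck * 1e3))
  invisible(x)
}
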