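#' Build the parent-artery centerline
#'
#' The centerline is a constant-curvature arc (a straight segment when
#' `CP = 0`) in the z = 0 plane, with the inlet at the origin and the inlet
#' tangent along +x. The sac attaches at arc length `s_sac` with 10 parent
#' diameters of artery upstream (fully developed inflow) and 5 diameters
#' downstream. For strongly curved, wide arteries the downstream run is
#' shortened so the total swept angle stays below `max_angle` and the tube
#' cannot self-intersect.
#'
#' All centerline quantities are in SI meters / 1/m (morphological
#' parameters are mm at the interface).
#'
#' @param params an `aneurysm_params` object.
#' @param upstream,downstream artery length before/after the sac, in parent
#'   diameters.
#' @param max_angle cap on the total swept angle, radians.
#' @return object of class `centerline` with fields `k` (curvature 1/m),
#'   `R` (radius of curvature, `Inf` when straight), `L` (length m),
#'   `s_sac` (sac arc-length station m).
#' @export
build_centerline <- function(params, upstream = 10, downstream = 5,
                             max_angle = 4.5) {
  stopifnot(inherits(params, "aneurysm_params"))
  DP <- params$DP * 1e-3              # m
  k  <- params$CP * 1e3               # 1/m
  up <- upstream * DP
  dn <- downstream * DP
  if (k > 0) {
    # keep the arc well clear of closing on itself
    r_tube <- DP / 2
    Rc <- 1 / k
    theta_cap <- min(max_angle, 2 * pi - 2 * asin(min(0.95, r_tube / Rc)) - 0.35)
    if (k * (up + dn) > theta_cap)
      dn <- max(2 * DP, theta_cap / k - up)
  }
  structure(list(
    k = k,
    R = if (k > 0) 1 / k else Inf,
    L = up + dn,
    s_sac = up,
    curvature = k
  ), class = "centerline")
}

#' Local Frenet-style frame along the centerline
#'
#' Returns position, unit tangent and the outward radial unit normal
#' (pointing away from the center of curvature; +y for a straight artery)
#' at arc lengths `s`. The binormal is +z everywhere (planar centerline).
#'
#' @param cl a `centerline` object.
#' @param s numeric vector of arc lengths, m.
#' @return list of n x 3 matrices `point`, `tangent`, `normal`.
#' @export
centerline_frame <- function(cl, s) {
  s <- as.numeric(s)
  n <- length(s)
  if (cl$k == 0) {
    list(point   = unname(cbind(s, 0, 0)),
         tangent = matrix(c(1, 0, 0), n, 3, byrow = TRUE),
         normal  = matrix(c(0, 1, 0), n, 3, byrow = TRUE))
  } else {
    R <- cl$R
    th <- s * cl$k
    list(point   = cbind(R * sin(th), R * cos(th) - R, 0),
         tangent = cbind(cos(th), -sin(th), 0),
         normal  = cbind(sin(th), cos(th), 0))
  }
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: length %.1f mm, curvature %.4f 1/mm, sac at %.1f mm\n",
              x$L * 1e3, x$k * 1e-3, x$s_sac * 1e3))
  invisible(x)
}
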