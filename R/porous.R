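#' Blood material properties
#'
#' @param rho density, kg/m^3 (default 1050).
#' @param mu dynamic viscosity, Pa.s (default 0.0035).
#' @return object of class `fluid_props`.
#' @export
fluid_props <- function(rho = 1050, mu = 0.0035) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_props")
}

#' Porous-medium flow-diverter layer specification
#'
#' The stent wire mesh is represented as a thin continuum layer across the
#' aneurysm neck with Darcy permeability `K` and inertial loss coefficient
#' `C`.
#'
#' @param thickness layer thickness, m (default 150e-6).
#' @param K permeability, m^2 (default 0.001489 mm^2 = 1.489e-9 m^2).
#' @param C inertial loss coefficient, 1/m (default 7665).
#' @return object of class `porous_layer`.
#' @export
porous_layer <- function(thickness = 150e-6, K = 1.489e-9, C = 7665) {
  stopifnot(thickness > 0, K > 0, C > 0)
  structure(list(thickness = thickness, K = K, C = C), class = "porous_layer")
}

#' Darcy-Forchheimer momentum source of the porous layer
#'
#' Per-component momentum sink `S_i = -(mu/K * v_i + C * rho/2 * |v| * v_i)`
#' (Pa/m): a viscous Darcy term plus an inertial Forchheimer term, always
#' antiparallel to the velocity.
#'
#' @param v velocity, length-3 vector or n x 3 matrix, m/s.
#' @param props a `fluid_props`.
#' @param layer a `porous_layer`.
#' @return momentum source with the shape of `v`, Pa/m.
#' @export
source_term <- function(v, props = fluid_props(), layer = porous_layer()) {
  m <- rbind(v)
  if (!all(is.finite(m))) stop("source_term: non-finite velocity input")
  speed <- vec_norm(m)
  s <- -(props$mu / layer$K) * m - layer$C * 0.5 * props$rho * speed * m
  if (is.matrix(v)) s else as.numeric(s)
}

#' Pressure drop across the porous layer
#'
#' The thin-layer reduction of the volumetric momentum sink: integrating the
#' source magnitude across the layer thickness gives
#' `dP = thickness * (mu/K * v_n + C * rho/2 * v_n^2)` for normal
#' approach speed `v_n >= 0`.
#'
#' @param v_n normal speed through the layer, m/s (vectorized).
#' @inheritParams source_term
#' @return pressure drop, Pa (>= 0, convex increasing in `v_n`).
#' @export
pressure_drop <- function(v_n, props = fluid_props(), layer = porous_layer()) {
  if (any(v_n < 0)) stop("pressure_drop: negative normal speed (orientation error)")
  layer$thickness * (props$mu / layer$K * v_n +
                       layer$C * 0.5 * props$rho * v_n^2)
}

#' Velocity transmission factor of the porous layer
#'
#' Fraction `v_through / v_approach` in (0, 1], where `v_through` is the
#' speed a driving pressure `driving_dp` pushes through the layer:
#' the positive root of
#' `thickness * (mu/K * v + C * rho/2 * v^2) = driving_dp`, capped at 1.
#'
#' @param v_approach approach speed, m/s (> 0 for a meaningful ratio).
#' @param driving_dp driving pressure, Pa (> 0).
#' @inheritParams source_term
#' @return dimensionless factor in (0, 1].
#' @export
transmission_factor <- function(v_approach, driving_dp,
                                props = fluid_props(), layer = porous_layer()) {
  stopifnot(all(v_approach >= 0), all(driving_dp > 0))
  a <- layer$thickness * layer$C * 0.5 * props$rho
  b <- layer$thickness * props$mu / layer$K
  v_through <- (-b + sqrt(b^2 + 4 * a * driving_dp)) / (2 * a)
  pmin(1, v_through / pmax(v_approach, .Machine$double.eps))
}
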