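#' Elastic-foundation material parameters
#'
#' Material constants of one deformable bearing layer (polyethylene insert or
#' lateral cartilage) for the Winkler elastic-foundation contact model, plus
#' the articular friction coefficient.
#'
#' @param youngs_modulus Young's modulus E (MPa).
#' @param poisson_ratio Poisson's ratio, in [0, 0.5) strictly (the foundation
#'   stiffness is singular at 0.5).
#' @param layer_thickness foundation layer thickness t (mm).
#' @param friction_coefficient Coulomb friction coefficient, default 0.04.
#' @return object of class \code{foundation_params}.
#' @export
foundation_params <- function(youngs_modulus, poisson_ratio, layer_thickness,
                              friction_coefficient = 0.04) {
  stopifnot(youngs_modulus > 0, layer_thickness > 0,
            friction_coefficient >= 0)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5) strictly", call. = FALSE)
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 layer_thickness = layer_thickness,
                 friction_coefficient = friction_coefficient),
            class = "foundation_params")
}

#' Winkler foundation stiffness of a bonded elastic layer
#'
#' Per-area spring constant of a thin bonded elastic layer in confined
#' compression:
#' \deqn{k = \frac{E (1 - \nu)}{(1 + \nu)(1 - 2\nu)\, t}}
#' in N/mm^3; pressure at a node is k times its penetration.
#'
#' @param params a \code{\link{foundation_params}}.
#' @return foundation modulus k (N/mm^3).
#' @export
foundation_modulus <- function(params) {
  stopifnot(inherits(params, "foundation_params"))
  e <- params$youngs_modulus; nu <- params$poisson_ratio
  e * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * params$layer_thickness)
}

#' Kinematic state of the femoral component relative to the tibia
#'
#' Degrees of freedom tracked per gait sample. \code{ap_translation} is the
#' tibial anterior displacement (so the femur shifts posteriorly on the
#' insert by the same amount); \code{ie_rotation} is internal +.
#'
#' @param flexion flexion angle (deg).
#' @param ap_translation tibial AP displacement (mm, anterior +).
#' @param ie_rotation tibial IE rotation (deg, internal +).
#' @param axial_approach femoral axial approach / penetration DOF (mm).
#' @param vv_tilt varus--valgus tilt (deg, varus = medial-down +).
#' @return object of class \code{kinematic_state}.
#' @export
kinematic_state <- function(flexion = 0, ap_translation = 0, ie_rotation = 0,
                            axial_approach = 0, vv_tilt = 0) {
  structure(list(flexion = flexion, ap_translation = ap_translation,
                 ie_rotation = ie_rotation, axial_approach = axial_approach,
                 vv_tilt = vv_tilt),
            class = "kinematic_state")
}

# Femoral in-plane AP offset on a compartment: tibial anterior displacement u
# moves the femur posteriorly on the bearing surface; tibial internal
# rotation theta about the vertical axis through the joint centre shifts it
# by theta * (compartment ML lever).
femoral_ap_offset <- function(kin, center_z) {
  -kin$ap_translation + (kin$ie_rotation * pi / 180) * center_z
}

# Support height S(node): femoral apex height at which the node first
# touches. Penetration at apex height H(z) is S - H(z). -Inf where the
# femoral footprint does not cover the node.
compartment_support <- function(comp, x_off = 0) {
  drop <- femoral_drop(comp$femoral, comp$tibial$x - x_off, comp$tibial$z)
  s <- comp$datum + comp$tibial$height - drop
  s[!is.finite(s)] <- -Inf
  s
}

make_contact_solution <- function(comp, pressure, approach, slide = NULL) {
  active <- pressure > 0
  a <- comp$tibial$nodal_area
  total <- sum(pressure * a)
  X <- outer(comp$tibial$x, rep(1, length(comp$tibial$z)))
  Z <- outer(rep(1, length(comp$tibial$x)), comp$tibial$z)
  pa <- pressure * a
  cop <- if (total > 0) c(x = sum(pa * X) / total, z = sum(pa * Z) / total)
  else c(x = NA_real_, z = NA_real_)
  structure(list(pressure = pressure,
                 contact_area = sum(a[active]),
                 peak_pressure = if (any(active)) max(pressure) else 0,
                 total_force = total,
                 center_of_pressure = cop,
                 axial_approach = approach,
                 active = active,
                 slide_increment = slide),
            class = "contact_solution")
}

#' @export
print.contact_solution <- function(x, ...) {
  cat(sprintf(paste0("contact_solution: F = %.1f N, peak p = %.2f MPa, ",
                     "area = %.1f mm^2\n"),
              x$total_force, x$peak_pressure, x$contact_area))
  invisible(x)
}

#' Elastic-foundation contact solve for one compartment
#'
#' Finds the femoral axial position at which the foundation pressure field
#' \eqn{p = k \max(0, \mathrm{penetration})} integrates to the target normal
#' load, with flexion / AP / IE kinematics fixed and varus--valgus tilt held
#' at \code{kin$vv_tilt} (tilt is solved at joint level by
#' \code{\link{solve_joint_equilibrium}}, not per compartment). The femoral
#' surface is evaluated analytically at the translated position, so the
#' solve reduces to a monotone 1-D root find (safeguarded Newton on the
#' piecewise-linear force--approach curve) converged to a relative force
#' error of 1e-9, far inside the 0.1\% contract.
#'
#' @param geom a \code{\link{compartment_geometry}}.
#' @param kin a \code{\link{kinematic_state}} (flexion, AP, IE, tilt fixed).
#' @param target_load normal load to carry (N), >= 0.
#' @param foundation a \code{\link{foundation_params}} for the layer.
#' @param z_pivot joint ML coordinate about which \code{vv_tilt} is applied
#'   (mm), default 0.
#' @return object of class \code{contact_solution}: per-node pressure (MPa),
#'   contact area (mm^2, summed nodal area of loaded nodes), peak pressure,
#'   total force, centre of pressure (compartment-local mm) and the solved
#'   axial approach (mm, penetration at the deepest node).
#' @export
solve_contact <- function(geom, kin = kinematic_state(), target_load,
                          foundation, z_pivot = 0) {
  stopifnot(inherits(geom, "compartment_geometry"), target_load >= 0)
  k <- foundation_modulus(foundation)
  s <- compartment_support(geom, femoral_ap_offset(kin, geom$center_z))
  phi <- kin$vv_tilt * pi / 180
  zg <- outer(rep(1, length(geom$tibial$x)), geom$tibial$z) + geom$center_z
  s_eff <- s + phi * (zg - z_pivot)  # tilt folded into the support height
  a <- geom$tibial$nodal_area
  if (target_load == 0) {
    p <- matrix(0, nrow(s), ncol(s))
    return(make_contact_solution(geom, p, approach = 0))
  }
  touch <- max(s_eff)
  if (!is.finite(touch))
    stop("femoral footprint does not cover the bearing surface", call. = FALSE)
  travel <- 2 * geom$layer_thickness
  force_at <- function(h0) {
    pen <- s_eff - h0
    sum(k * pmax(0, pen) * a)
  }
  if (force_at(touch - travel) < target_load)
    stop("target load not attainable within the travel bound", call. = FALSE)
  h0 <- solve_monotone_force(force_at, target_load, touch, touch - travel,
                             dforce = function(h0) {
                               act <- s_eff > h0
                               -k * sum(a[act])
                             })
  pen <- pmax(0, s_eff - h0)
  make_contact_solution(geom, k * pen, approach = max(pen))
}

# Root of force_at(h) = target for a force that decreases monotonically in h
# on [h_lo_force_side = hi... ]: bracket [lo, hi] with force(hi) <= target <=
# force(lo). Safeguarded Newton using the analytic derivative; bisection
# fallback. Relative tolerance 1e-9.
solve_monotone_force <- function(force_at, target, hi, lo, dforce,
                                 tol = 1e-9, max_iter = 200L) {
  f_hi <- force_at(hi); f_lo <- force_at(lo)
  if (f_hi > target || f_lo < target)
    stop("load target not bracketed by the travel bounds", call. = FALSE)
  h <- hi - (hi - lo) * 0.01
  for (it in seq_len(max_iter)) {
    f <- force_at(h)
    if (abs(f - target) <= tol * max(target, 1)) return(h)
    if (f > target) lo <- h else hi <- h
    d <- dforce(h)
    h_new <- if (is.finite(d) && d < 0) h - (f - target) / d else NA_real_
    if (!is.finite(h_new) || h_new <= lo || h_new >= hi)
      h_new <- (lo + hi) / 2
    h <- h_new
  }
  stop("contact solver did not converge", call. = FALSE)
}

#' Per-node sliding increment between consecutive gait samples
#'
#' Magnitude of the relative tangential displacement of the femoral surface
#' with respect to the bearing surface across one time increment, composed
#' vectorially in the tangent plane from three contributions: the flexion
#' arc (local femoral sagittal radius times the flexion increment), the AP
#' translation increment, and the IE rotation increment acting about the
#' vertical axis through the joint centre with the node's in-plane lever arm.
#'
#' @param geom a \code{\link{compartment_geometry}}.
#' @param kin_t,kin_t_next \code{\link{kinematic_state}}s at the increment
#'   start and end.
#' @param active optional logical matrix of contacting nodes; sliding is
#'   reported as zero elsewhere.
#' @return matrix of sliding magnitudes (mm) over the bearing lattice.
#' @export
sliding_increment <- function(geom, kin_t, kin_t_next, active = NULL) {
  rs <- geom$femoral$analytic$sagittal_radius
  dflex <- (kin_t_next$flexion - kin_t$flexion) * pi / 180
  dth <- (kin_t_next$ie_rotation - kin_t$ie_rotation) * pi / 180
  du <- kin_t_next$ap_translation - kin_t$ap_translation
  x <- geom$tibial$x; z <- geom$tibial$z
  zg <- outer(rep(1, length(x)), z) + geom$center_z
  xg <- outer(x, rep(1, length(z)))
  sx <- rs * dflex - du + dth * zg
  sz <- -dth * xg
  slide <- sqrt(sx^2 + sz^2)
  if (!is.null(active)) slide[!active] <- 0
  slide
}
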