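# Periodic smooth bump on the unit circle (von-Mises-shaped kernel):
# 1 at t = t0, decaying with angular distance; exactly 1-periodic.
periodic_bump <- function(t, t0, kappa) {
  exp(kappa * (cos(2 * pi * (t - t0)) - 1))
}

#' ISO-14243-style gait waveform set
#'
#' Generates one gait cycle of flexion angle, axial force, AP force and
#' internal--external (IE) torque as sums of smooth periodic bumps, the
#' force-controlled loading style of knee-wear testing. The axial-force curve
#' carries two stance peaks whose amplitudes are solved exactly so that the
#' configured peak values are attained at the configured phases (defaults:
#' 2600 N at 13\% cycle and 2433.5 N at 45\% cycle) above a broad mid-stance
#' plateau and a swing-phase baseline. Flexion follows a periodic spline
#' through ISO-shaped control points (stance flexion peak ~14 deg, dip in
#' mid-stance, steep rise from late stance to a 58 deg swing peak); AP
#' force and IE torque are stance-dominated bursts. Sign conventions: AP
#' force positive = anteriorly directed on the tibia; IE torque positive =
#' internal.
#'
#' @param n_samples samples per cycle (>= 50), default 100; sample k sits at
#'   cycle fraction (k-1)/n_samples, so the default lattice contains the
#'   default peak phases exactly.
#' @param axial_peak1,axial_phase1 first stance peak (N) and its phase.
#' @param axial_peak2,axial_phase2 second stance peak (N) and its phase.
#' @param axial_baseline swing-phase axial force floor (N).
#' @param axial_plateau,axial_plateau_phase,axial_plateau_kappa broad
#'   mid-stance plateau bump (N, phase, sharpness).
#' @param axial_kappa sharpness of the two peak bumps.
#' @param flexion_points data.frame with columns \code{t} (cycle fraction,
#'   first 0 and last 1 with equal angles) and \code{deg}; interpolated by a
#'   periodic cubic spline.
#' @param ap_amp1,ap_amp2,ap_amp_swing AP-force bump amplitudes (N).
#' @param ie_amp1,ie_amp2,ie_amp_swing IE-torque bump amplitudes (N m).
#' @return object of class \code{gait_waveforms}: list with vectors \code{t}
#'   (cycle fraction in [0,1)), \code{flexion} (deg), \code{axial_force} (N),
#'   \code{ap_force} (N), \code{ie_torque} (N m).
#' @export
make_iso14243_waveforms <- function(n_samples = 100,
                                    axial_peak1 = 2600, axial_phase1 = 0.13,
                                    axial_peak2 = 2433.5, axial_phase2 = 0.45,
                                    axial_baseline = 168,
                                    axial_plateau = 900,
                                    axial_plateau_phase = 0.29,
                                    axial_plateau_kappa = 10,
                                    axial_kappa = 40,
                                    flexion_points = data.frame(
                                      t = c(0, 0.10, 0.20, 0.30, 0.40, 0.50,
                                            0.60, 0.70, 0.80, 0.90, 1),
                                      deg = c(0, 12, 14, 8, 10, 25,
                                              45, 58, 30, 5, 0)),
                                    ap_amp1 = 120, ap_amp2 = 180,
                                    ap_amp_swing = -60,
                                    ie_amp1 = 1.0, ie_amp2 = 2.5,
                                    ie_amp_swing = -0.8) {
  if (n_samples < 50) stop("n_samples must be >= 50", call. = FALSE)
  for (ph in c(axial_phase1, axial_phase2))
    if (ph <= 0 || ph >= 1)
      stop("axial peak phases must lie strictly inside (0, 1)", call. = FALSE)
  if (axial_baseline < 0) stop("axial baseline must be >= 0", call. = FALSE)
  t <- (seq_len(n_samples) - 1L) / n_samples

  # Solve the two peak-bump amplitudes so the total axial force equals the
  # configured values exactly at the configured phases.
  plateau_at <- function(tt) axial_plateau *
    periodic_bump(tt, axial_plateau_phase, axial_plateau_kappa)
  g11 <- 1
  g12 <- periodic_bump(axial_phase1, axial_phase2, axial_kappa)
  g21 <- periodic_bump(axial_phase2, axial_phase1, axial_kappa)
  g22 <- 1
  rhs <- c(axial_peak1 - axial_baseline - plateau_at(axial_phase1),
           axial_peak2 - axial_baseline - plateau_at(axial_phase2))
  amps <- solve(matrix(c(g11, g21, g12, g22), 2L, 2L), rhs)
  if (any(amps < 0))
    stop("axial peak configuration not attainable above the plateau",
         call. = FALSE)
  axial <- axial_baseline + plateau_at(t) +
    amps[1L] * periodic_bump(t, axial_phase1, axial_kappa) +
    amps[2L] * periodic_bump(t, axial_phase2, axial_kappa)

  flexion_points <- as.data.frame(flexion_points)
  if (flexion_points$t[1L] != 0 ||
      flexion_points$t[nrow(flexion_points)] != 1 ||
      flexion_points$deg[1L] != flexion_points$deg[nrow(flexion_points)])
    stop("flexion_points must span t = 0..1 with equal end angles",
         call. = FALSE)
  flexion <- stats::spline(flexion_points$t, flexion_points$deg,
                           method = "periodic", xout = t)$y
  ap <- ap_amp1 * periodic_bump(t, axial_phase1, 25) +
    ap_amp2 * periodic_bump(t, axial_phase2, 25) +
    ap_amp_swing * periodic_bump(t, 0.75, 30)
  ie <- ie_amp1 * periodic_bump(t, axial_phase1, 25) +
    ie_amp2 * periodic_bump(t, axial_phase2, 25) +
    ie_amp_swing * periodic_bump(t, 0.78, 30)

  structure(list(t = t, flexion = flexion, axial_force = axial,
                 ap_force = ap, ie_torque = ie),
            class = "gait_waveforms")
}

#' @export
print.gait_waveforms <- function(x, ...) {
  cat(sprintf("gait_waveforms: %d samples/cycle\n", length(x$t)))
  cat(sprintf("  axial force %.0f-%.0f N, flexion %.1f-%.1f deg\n",
              min(x$axial_force), max(x$axial_force),
              min(x$flexion), max(x$flexion)))
  invisible(x)
}

#' Write / read gait waveforms as CSV
#'
#' Columns: \code{t, flexion_deg, axial_N, ap_N, ie_Nm}.
#'
#' @param waveforms a \code{gait_waveforms} object.
#' @param path file path.
#' @return \code{read_waveforms_csv} returns a \code{gait_waveforms}.
#' @export
write_waveforms_csv <- function(waveforms, path) {
  df <- data.frame(t = waveforms$t, flexion_deg = waveforms$flexion,
                   axial_N = waveforms$axial_force,
                   ap_N = waveforms$ap_force, ie_Nm = waveforms$ie_torque)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms_csv
#' @export
read_waveforms_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(t = df$t, flexion = df$flexion_deg,
                 axial_force = df$axial_N, ap_force = df$ap_N,
                 ie_torque = df$ie_Nm),
            class = "gait_waveforms")
}

#' Lumped soft-tissue restraint parameters
#'
#' Passive restraints of the replaced knee during gait: a linear torsion
#' spring on internal--external rotation (0.6 N m/deg) and an odd nonlinear
#' (linear + cubic) anterior--posterior force law, both acting only beyond a
#' neutral zone within which the soft tissues produce no force.
#'
#' @param ie_spring_stiffness IE torsional stiffness beyond the neutral zone
#'   (N m/deg), default 0.6.
#' @param ap_linear linear AP coefficient on the excess displacement (N/mm).
#' @param ap_cubic cubic AP coefficient (N/mm^3).
#' @param ap_neutral_zone half-width of the AP neutral zone (mm).
#' @param ie_neutral_zone half-width of the IE neutral zone (deg).
#' @return object of class \code{restraint_params}.
#' @export
restraint_params <- function(ie_spring_stiffness = 0.6,
                             ap_linear = 30, ap_cubic = 30,
                             ap_neutral_zone = 2.5, ie_neutral_zone = 3) {
  stopifnot(ie_spring_stiffness >= 0, ap_linear >= 0, ap_cubic >= 0,
            ap_neutral_zone >= 0, ie_neutral_zone >= 0)
  structure(list(ie_spring_stiffness = ie_spring_stiffness,
                 ap_linear = ap_linear, ap_cubic = ap_cubic,
                 ap_neutral_zone = ap_neutral_zone,
                 ie_neutral_zone = ie_neutral_zone),
            class = "restraint_params")
}

#' Soft-tissue restraint torque on IE rotation
#'
#' Zero inside the neutral zone; beyond it, linear in the excess rotation
#' with slope \code{ie_spring_stiffness}, opposing the rotation (odd
#' function).
#'
#' @param ie_rotation IE rotation (deg), vectorized.
#' @param params a \code{\link{restraint_params}}.
#' @return restraint torque (N m), sign opposite to the rotation.
#' @export
restraint_torque <- function(ie_rotation, params = restraint_params()) {
  excess <- pmax(0, abs(ie_rotation) - params$ie_neutral_zone)
  -sign(ie_rotation) * params$ie_spring_stiffness * excess
}

#' Soft-tissue restraint force on AP displacement
#'
#' Zero inside the neutral zone; beyond it, a monotone odd linear-plus-cubic
#' law on the excess displacement, opposing the displacement.
#'
#' @param ap_displacement AP displacement (mm, anterior +), vectorized.
#' @param params a \code{\link{restraint_params}}.
#' @return restraint force (N), sign opposite to the displacement.
#' @export
restraint_force_ap <- function(ap_displacement, params = restraint_params()) {
  excess <- pmax(0, abs(ap_displacement) - params$ap_neutral_zone)
  -sign(ap_displacement) * (params$ap_linear * excess +
                              params$ap_cubic * excess^3)
}

# Invert the odd AP law: displacement whose restraint balances `force`
# (restraint(u) = -force). Monotone; solved in closed bracketed form.
invert_ap_restraint <- function(force, params) {
  m <- abs(force)
  if (m < .Machine$double.eps) return(0)
  if (params$ap_linear == 0 && params$ap_cubic == 0)
    stop("AP restraint law is identically zero; equilibrium undefined",
         call. = FALSE)
  f <- function(e) params$ap_linear * e + params$ap_cubic * e^3 - m
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  e <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  sign(force) * (params$ap_neutral_zone + e)
}

invert_ie_restraint <- function(torque, params) {
  if (abs(torque) < .Machine$double.eps) return(0)
  if (params$ie_spring_stiffness == 0)
    stop("IE restraint stiffness is zero; equilibrium undefined",
         call. = FALSE)
  sign(torque) * (params$ie_neutral_zone +
                    abs(torque) / params$ie_spring_stiffness)
}

# One stick-slip update of a frictional quasi-static DOF: `applied` is the
# external load, `restraint(u)` the (odd, monotone) soft-tissue law,
# `invert(f)` its exact inverse, `cap` the Coulomb capacity (mu N [lever]).
# If the unbalanced load at the previous position is within the capacity the
# DOF sticks (static friction closes the balance exactly); otherwise it
# slips to the position where applied - cap*sign(motion) + restraint = 0.
stick_slip_update <- function(u_prev, applied, cap, restraint, invert) {
  g <- applied + restraint(u_prev)
  if (abs(g) <= cap) return(u_prev)
  u <- invert(applied - cap * sign(g))
  # If kinetic friction would reverse the implied motion, the DOF sticks at
  # the point where the driving load just equals the capacity.
  if (sign(u - u_prev) != sign(g)) return(u_prev)
  u
}

#' Quasi-static AP / IE equilibrium over a gait cycle
#'
#' At each cycle sample, solves the tibial AP displacement and IE rotation
#' from static equilibrium of the released degrees of freedom: applied load
#' + Coulomb friction traction + soft-tissue restraint = 0. Friction is
#' treated with stick--slip logic: when the unbalanced load at the current
#' position is within the Coulomb capacity \eqn{\mu N} (times the
#' centre-of-pressure lever for the IE torque balance), static friction
#' closes the balance and the tibia holds its position; beyond it, the DOF
#' slips to the position where the kinetic-friction balance holds, obtained
#' by exact inversion of the monotone restraint law (residuals at machine
#' precision, far inside the 0.01 N / 0.001 N m contract). Normal force and
#' lever come from \code{contact_state}; omitting it solves the
#' frictionless balance. Two laps of the cycle are marched and the second
#' kept, so the returned trajectory is insensitive to the arbitrary start
#' position.
#'
#' @param waveforms a \code{gait_waveforms}.
#' @param params a \code{\link{restraint_params}}.
#' @param contact_state optional list with per-sample \code{normal_force} (N),
#'   \code{cop_radius} (mm, IE lever arm of the friction traction) and
#'   \code{friction_coefficient}.
#' @return data.frame with one row per sample: \code{t}, \code{ap_mm},
#'   \code{ie_deg}, \code{residual_ap_N}, \code{residual_ie_Nm} (the
#'   residuals include the friction reaction; zero in stick by
#'   construction).
#' @export
quasi_static_ap_ie <- function(waveforms, params = restraint_params(),
                               contact_state = NULL) {
  n <- length(waveforms$t)
  mu <- 0; N <- rep(0, n); lever <- 25
  if (!is.null(contact_state)) {
    mu <- contact_state$friction_coefficient
    N <- rep_len(contact_state$normal_force, n)
    if (!is.null(contact_state$cop_radius))
      lever <- contact_state$cop_radius
  }
  ap <- numeric(n); ie <- numeric(n)
  res_ap <- numeric(n); res_ie <- numeric(n)
  u <- 0; th <- 0
  for (lap in 1:2) for (i in seq_len(n)) {
    cap_f <- mu * N[i]
    cap_t <- mu * N[i] * (lever / 1000)
    u <- stick_slip_update(u, waveforms$ap_force[i], cap_f,
                           function(x) restraint_force_ap(x, params),
                           function(f) invert_ap_restraint(f, params))
    th <- stick_slip_update(th, waveforms$ie_torque[i], cap_t,
                            function(x) restraint_torque(x, params),
                            function(f) invert_ie_restraint(f, params))
    if (lap == 2L) {
      ap[i] <- u; ie[i] <- th
      g_f <- waveforms$ap_force[i] + restraint_force_ap(u, params)
      g_t <- waveforms$ie_torque[i] + restraint_torque(th, params)
      res_ap[i] <- g_f - sign(g_f) * min(abs(g_f), cap_f)
      res_ie[i] <- g_t - sign(g_t) * min(abs(g_t), cap_t)
      if (abs(res_ap[i]) > 0.01 || abs(res_ie[i]) > 0.001)
        stop(sprintf("quasi-static equilibrium failed at sample %d (t = %.2f)",
                     i, waveforms$t[i]), call. = FALSE)
    }
  }
  data.frame(t = waveforms$t, ap_mm = ap, ie_deg = ie,
             residual_ap_N = res_ap, residual_ie_Nm = res_ie)
}
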