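#' Whole-joint configuration for two-compartment load sharing
#'
#' Placement of the femoral axial-load point and the two compartment centres
#' in joint mediolateral coordinates (medial +, joint centre 0), plus the
#' varus--valgus (VV) degrees of freedom. The load point sits 5.0 mm medial
#' of the femoral flexion--extension axis centre, the ISO 14243 convention
#' for whole-knee loading. \code{vv_tilt_limit} is a passive soft-tissue
#' restraint on VV tilt: when the moment balance would demand more tilt than
#' the limit, the tilt is pinned there and the residual moment is reported
#' (the collateral structures, not the articulation, then carry it).
#' \code{vv_restraint_stiffness} is the lumped varus--valgus stiffness of
#' the retained ligamentous envelope (collaterals, cruciates, capsule)
#' about the balanced reference tilt \code{vv_reference_tilt}: the soft
#' tissue is taken as tension-balanced in the unworn standing posture, so
#' only deviations from that posture — such as the femur settling varus
#' into a progressively worn medial pocket — draw a restoring moment. Zero
#' stiffness recovers the pure two-point contact moment balance.
#'
#' @param femoral_load_offset load-point offset, mm medial of the joint
#'   centre (default 5.0).
#' @param medial_center_z,lateral_center_z compartment centres (mm); must lie
#'   on opposite sides of the joint centre.
#' @param vv_free solve VV tilt from the moment balance (default TRUE);
#'   FALSE holds tilt at zero.
#' @param vv_tilt_limit passive VV tilt bound (deg), default 10.
#' @param vv_restraint_stiffness lumped soft-tissue VV stiffness (N m/deg),
#'   default 30 (loaded-knee envelope); >= 0.
#' @param vv_reference_tilt balanced reference tilt of the restraint (deg),
#'   default 0; \code{\link{build_scenario}} sets it to the unworn
#'   free-equilibrium tilt at the first axial peak.
#' @return object of class \code{joint_config}.
#' @export
joint_config <- function(femoral_load_offset = 5.0,
                         medial_center_z = 25, lateral_center_z = -25,
                         vv_free = TRUE, vv_tilt_limit = 10,
                         vv_restraint_stiffness = 30,
                         vv_reference_tilt = 0) {
  stopifnot(is.finite(femoral_load_offset), vv_tilt_limit > 0,
            vv_restraint_stiffness >= 0, is.finite(vv_reference_tilt))
  if (!(medial_center_z > 0 && lateral_center_z < 0))
    stop("compartment centres must lie on opposite sides of the joint centre",
         call. = FALSE)
  structure(list(femoral_load_offset = femoral_load_offset,
                 medial_center_z = medial_center_z,
                 lateral_center_z = lateral_center_z,
                 vv_free = vv_free, vv_tilt_limit = vv_tilt_limit,
                 vv_restraint_stiffness = vv_restraint_stiffness,
                 vv_reference_tilt = vv_reference_tilt),
            class = "joint_config")
}

#' Balance the two compartments of a whole-joint model
#'
#' Shifts the lateral compartment's vertical datum so that, with the femur
#' untilted and centred, both compartments reach first contact at the same
#' femoral height — the surrogate for a ligament-balanced knee with a
#' restored joint line. Run once at scenario setup.
#'
#' @param medial,lateral \code{\link{compartment_geometry}} objects.
#' @return the lateral compartment with its datum adjusted.
#' @export
balance_compartments <- function(medial, lateral) {
  touch_m <- max(compartment_support(medial))
  touch_l <- max(compartment_support(lateral))
  lateral$datum <- lateral$datum + (touch_m - touch_l)
  lateral
}

#' Two-compartment joint equilibrium (whole-joint scenario)
#'
#' Solves the femoral axial position and varus--valgus tilt jointly so that
#' (i) the foundation-pressure integrals over both compartments sum to the
#' applied axial force and (ii) the VV moment of those pressures about the
#' femoral load point, together with the lumped ligamentous restraint
#' moment, vanishes — no load-sharing ratio is imposed. The
#' force balance at fixed tilt is a monotone 1-D solve; the moment is
#' strictly increasing in tilt along that constraint (Schur-complement
#' positivity of the foundation stiffness), so the outer solve is a
#' safeguarded 1-D Newton as well. If the moment cannot be zeroed within the
#' passive tilt limit the tilt is pinned at the bound and the residual
#' moment reported.
#'
#' @param medial,lateral \code{\link{compartment_geometry}} objects (the
#'   lateral one already \code{\link{balance_compartments}}-ed).
#' @param axial_force applied axial force (N), >= 0.
#' @param cfg a \code{\link{joint_config}}.
#' @param foundation_medial,foundation_lateral
#'   \code{\link{foundation_params}} per compartment.
#' @param kin_medial,kin_lateral \code{\link{kinematic_state}}s (flexion /
#'   AP / IE fixed per compartment).
#' @return list with \code{split} (class \code{load_split}: \code{f_medial},
#'   \code{f_lateral}, \code{medial_fraction}, \code{vv_tilt} deg,
#'   \code{moment_residual} N m), \code{medial} and \code{lateral}
#'   \code{contact_solution}s.
#' @export
solve_joint_equilibrium <- function(medial, lateral, axial_force,
                                    cfg = joint_config(),
                                    foundation_medial, foundation_lateral,
                                    kin_medial = kinematic_state(),
                                    kin_lateral = kin_medial) {
  stopifnot(axial_force >= 0)
  km <- foundation_modulus(foundation_medial)
  kl <- foundation_modulus(foundation_lateral)
  z_lp <- cfg$femoral_load_offset

  prep <- function(comp, kin, k) {
    s <- compartment_support(comp, femoral_ap_offset(kin, comp$center_z))
    zg <- outer(rep(1, length(comp$tibial$x)), comp$tibial$z) + comp$center_z
    keep <- is.finite(s)
    list(s = s[keep], w = (zg - z_lp)[keep], a = comp$tibial$nodal_area[keep],
         k = k, keep = keep, comp = comp)
  }
  pm <- prep(medial, kin_medial, km)
  pl <- prep(lateral, kin_lateral, kl)
  s_all <- c(pm$s, pl$s); w_all <- c(pm$w, pl$w); a_all <- c(pm$a, pl$a)
  ka <- c(rep(pm$k, length(pm$s)), rep(pl$k, length(pl$s))) * a_all

  if (axial_force == 0) {
    zero <- function(p) {
      pr <- matrix(0, length(p$comp$tibial$x), length(p$comp$tibial$z))
      make_contact_solution(p$comp, pr, approach = 0)
    }
    split <- structure(list(f_medial = 0, f_lateral = 0,
                            medial_fraction = NA_real_, vv_tilt = 0,
                            moment_residual = 0, axial_force = 0),
                       class = "load_split")
    return(list(split = split, medial = zero(pm), lateral = zero(pl)))
  }

  pen_all <- function(h0, phi) pmax(0, s_all + phi * w_all - h0)
  force_at <- function(h0, phi) sum(ka * pen_all(h0, phi))
  travel <- 2 * max(medial$layer_thickness, lateral$layer_thickness) +
    abs(cfg$vv_tilt_limit * pi / 180) *
    diff(range(c(pm$w, pl$w)))
  solve_h0 <- function(phi) {
    touch <- max(s_all + phi * w_all)
    solve_monotone_force(function(h) force_at(h, phi), axial_force,
                         touch, touch - travel,
                         dforce = function(h) {
                           act <- (s_all + phi * w_all) > h
                           -sum(ka[act])
                         })
  }
  # Lumped ligamentous VV restraint: restoring moment (N mm) about the
  # balanced reference tilt; its stiffness adds to the contact moment
  # gradient, preserving monotonicity.
  k_vv <- cfg$vv_restraint_stiffness * 180 / pi * 1000   # N mm per rad
  phi_ref <- cfg$vv_reference_tilt * pi / 180
  moment_at <- function(phi) {
    h0 <- solve_h0(phi)
    pen <- pen_all(h0, phi)
    list(m = sum(ka * pen * w_all) + k_vv * (phi - phi_ref),
         h0 = h0, pen = pen)
  }
  # d(moment)/d(phi) along the force constraint: Schur complement of the
  # active-set foundation stiffness (strictly positive) plus the restraint
  # stiffness — the total moment is monotone increasing in tilt.
  dmoment <- function(phi, h0) {
    act <- (s_all + phi * w_all) > h0
    sk <- sum(ka[act]); skw <- sum((ka * w_all)[act])
    skw2 <- sum((ka * w_all^2)[act])
    skw2 - skw^2 / sk + k_vv
  }

  lim <- cfg$vv_tilt_limit * pi / 180
  if (!cfg$vv_free) {
    phi <- 0
    mres <- moment_at(0)
  } else {
    m_lo <- moment_at(-lim); m_hi <- moment_at(lim)
    if (m_lo$m >= 0) { phi <- -lim; mres <- m_lo }
    else if (m_hi$m <= 0) { phi <- lim; mres <- m_hi }
    else {
      lo <- -lim; hi <- lim; phi <- 0
      mres <- moment_at(phi)
      converged <- FALSE
      for (it in seq_len(200L)) {
        if (abs(mres$m) <= 0.1) { converged <- TRUE; break }  # 1e-4 N m in N mm
        if (mres$m > 0) hi <- phi else lo <- phi
        d <- dmoment(phi, mres$h0)
        phi_new <- if (is.finite(d) && d > 0) phi - mres$m / d else NA_real_
        if (!is.finite(phi_new) || phi_new <= lo || phi_new >= hi)
          phi_new <- (lo + hi) / 2
        phi <- phi_new
        mres <- moment_at(phi)
      }
      if (!converged && abs(mres$m) > 0.1)
        stop("joint equilibrium solver did not converge (moment residual ",
             signif(mres$m / 1000, 3), " N m)", call. = FALSE)
    }
  }

  h0 <- mres$h0
  pen <- mres$pen
  n_m <- length(pm$s)
  sol_of <- function(p, pen_part) {
    pr <- matrix(0, length(p$comp$tibial$x), length(p$comp$tibial$z))
    pr[p$keep] <- p$k * pen_part
    make_contact_solution(p$comp, pr,
                          approach = if (length(pen_part)) max(pen_part) else 0)
  }
  sol_m <- sol_of(pm, pen[seq_len(n_m)])
  sol_l <- sol_of(pl, pen[-seq_len(n_m)])
  fm <- sol_m$total_force; fl <- sol_l$total_force
  split <- structure(list(f_medial = fm, f_lateral = fl,
                          medial_fraction = fm / (fm + fl),
                          vv_tilt = phi * 180 / pi,
                          moment_residual = mres$m / 1000,
                          axial_force = axial_force),
                     class = "load_split")
  list(split = split, medial = sol_m, lateral = sol_l)
}

#' @export
print.load_split <- function(x, ...) {
  cat(sprintf(paste0("load_split: medial %.1f N, lateral %.1f N ",
                     "(medial fraction %.3f), VV tilt %.2f deg\n"),
              x$f_medial, x$f_lateral, x$medial_fraction, x$vv_tilt))
  invisible(x)
}

#' Confined-compression von Mises surrogate for cartilage
#'
#' Equivalent stress of a laterally confined uniaxial-strain state under a
#' surface pressure p: out-of-plane stress p, in-plane stresses
#' \eqn{\nu/(1-\nu)\,p}, giving
#' \deqn{\sigma_{vM} = p\,\frac{1 - 2\nu}{1 - \nu}.}
#' Used as the desk-scale surrogate for the cartilage equivalent stress; it
#' understates free-edge FE peaks, so downstream comparisons are trend-based.
#'
#' @param pressure surface pressure (MPa), vectorized, >= 0.
#' @param poisson_ratio Poisson's ratio, in [0, 0.5) strictly.
#' @return von Mises stress (MPa).
#' @export
cartilage_von_mises <- function(pressure, poisson_ratio) {
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5) strictly", call. = FALSE)
  pressure * (1 - 2 * poisson_ratio) / (1 - poisson_ratio)
}

#' Lateral cartilage stress trajectory over a gait cycle
#'
#' Per-sample peak lateral foundation pressure and its confined-compression
#' von Mises surrogate, with the cycle maximum and its phase attached.
#'
#' @param t cycle-fraction samples.
#' @param lateral_solutions list of lateral \code{contact_solution}s, one per
#'   sample.
#' @param poisson_ratio cartilage Poisson's ratio.
#' @return data.frame (\code{t}, \code{peak_pressure_MPa},
#'   \code{peak_von_mises_MPa}) with attributes \code{cycle_max_von_mises}
#'   and \code{cycle_max_phase}.
#' @export
lateral_stress_trajectory <- function(t, lateral_solutions, poisson_ratio) {
  pk <- vapply(lateral_solutions, function(s) s$peak_pressure, numeric(1L))
  vm <- cartilage_von_mises(pk, poisson_ratio)
  out <- data.frame(t = t, peak_pressure_MPa = pk, peak_von_mises_MPa = vm)
  i <- which.max(vm)
  attr(out, "cycle_max_von_mises") <- vm[i]
  attr(out, "cycle_max_phase") <- t[i]
  out
}
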