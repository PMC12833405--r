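# One representative gait cycle on the current geometry.
#
# Returns per-sample medial pressures and slides (flattened bearing lattice
# x samples), per-sample load splits (UKAK) or medial forces (UKA), the
# lateral solutions (UKAK) and cycle summary metrics. `scen` is the internal
# scenario bundle assembled by build_scenario(); its AP/IE kinematics are
# precomputed there (friction traction on a fixed nominal share of the
# axial load), so wear alters contact, not the gait trajectory.
evaluate_gait_cycle <- function(scen) {
  wf <- scen$waveforms
  n <- length(wf$t)
  ukak <- identical(scen$scenario, "UKAK")
  kinem <- scen$kinematics
  kin_list <- scen$kin_list

  n_nodes <- length(scen$medial$tibial$x) * length(scen$medial$tibial$z)
  pressures <- matrix(0, n_nodes, n)
  slides <- matrix(0, n_nodes, n)
  actives <- vector("list", n)
  splits <- vector("list", n)
  lat_solutions <- if (ukak) vector("list", n) else NULL
  peak_p <- numeric(n); area <- numeric(n)
  cop_x <- numeric(n); cop_z <- numeric(n)
  f_med <- numeric(n)

  for (i in seq_len(n)) {
    if (ukak) {
      eq <- solve_joint_equilibrium(scen$medial, scen$lateral,
                                    wf$axial_force[i], scen$joint,
                                    scen$foundation_medial,
                                    scen$foundation_lateral,
                                    kin_medial = kin_list[[i]])
      sol <- eq$medial
      splits[[i]] <- eq$split
      lat_solutions[[i]] <- eq$lateral
    } else {
      sol <- solve_contact(scen$medial, kin_list[[i]], wf$axial_force[i],
                           scen$foundation_medial)
    }
    pressures[, i] <- as.vector(sol$pressure)
    actives[[i]] <- sol$active
    peak_p[i] <- sol$peak_pressure
    area[i] <- sol$contact_area
    cop_x[i] <- sol$center_of_pressure[["x"]]
    cop_z[i] <- sol$center_of_pressure[["z"]]
    f_med[i] <- sol$total_force
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    slides[, i] <- as.vector(sliding_increment(scen$medial, kin_list[[i]],
                                               kin_list[[j]], actives[[i]]))
  }

  cycle_summary <- data.frame(t = wf$t, axial_N = wf$axial_force,
                              f_medial_N = f_med,
                              peak_pressure_MPa = peak_p,
                              contact_area_mm2 = area,
                              cop_x = cop_x, cop_z = cop_z)
  if (ukak) {
    cycle_summary$f_lateral_N <-
      vapply(splits, function(s) s$f_lateral, numeric(1L))
    cycle_summary$medial_fraction <-
      vapply(splits, function(s) s$medial_fraction, numeric(1L))
    cycle_summary$vv_tilt_deg <-
      vapply(splits, function(s) s$vv_tilt, numeric(1L))
    cycle_summary$lat_peak_pressure_MPa <-
      vapply(lat_solutions, function(s) s$peak_pressure, numeric(1L))
    cycle_summary$lat_peak_vm_MPa <- cartilage_von_mises(
      cycle_summary$lat_peak_pressure_MPa,
      scen$foundation_lateral$poisson_ratio)
  }
  list(pressures = pressures, slides = slides, kinematics = kinem,
       cycle_summary = cycle_summary)
}

#' Run the adaptive wear schedule for one scenario
#'
#' The core simulation loop: for each analysis step, evaluate one
#' representative gait cycle on the current geometry (gait equilibrium, then
#' contact — routed through the two-compartment joint balance in the
#' whole-joint scenario), accumulate the cycle's Archard depth field, scale
#' it to the step's cycle count and recede the insert surface. Pressures
#' within a step are frozen at the step-start geometry. A final cycle is
#' evaluated on the fully worn geometry so the history carries states for
#' steps 0..n (step k = geometry after k updates).
#'
#' @param scen scenario bundle from \code{\link{build_scenario}}.
#' @return list with the final \code{wear_state}, the worn medial
#'   \code{compartment_geometry}, a per-step \code{history} data.frame
#'   (cycles, cumulative volume/mass, max depth, cycle peak pressure and
#'   max contact area, medial fraction and lateral stress at the first
#'   axial peak where applicable) and the first/last cycle summaries.
#' @export
run_wear_schedule <- function(scen) {
  params <- scen$wear
  state <- wear_state(scen$medial)
  i_peak <- which.min(abs(scen$waveforms$t - scen$peak_phase))
  rows <- vector("list", params$n_steps + 1L)
  first_cycle <- NULL; last_cycle <- NULL

  for (step in 0:params$n_steps) {
    cyc <- tryCatch(evaluate_gait_cycle(scen), error = function(e)
      stop(sprintf("wear step %d: %s", step, conditionMessage(e)),
           call. = FALSE))
    if (step == 0L) first_cycle <- cyc$cycle_summary
    last_cycle <- cyc$cycle_summary
    cs <- cyc$cycle_summary
    row <- data.frame(step = step, cycles = step * params$cycles_per_step,
                      volume_mm3 = state$volume_loss,
                      mass_mg = state$mass_loss,
                      max_depth_mm = max(state$depth),
                      peak_pressure_MPa = max(cs$peak_pressure_MPa),
                      contact_area_mm2 = max(cs$contact_area_mm2))
    if (identical(scen$scenario, "UKAK")) {
      row$medial_fraction_peak1 <- cs$medial_fraction[i_peak]
      row$lat_peak_vm_MPa <- max(cs$lat_peak_vm_MPa[
        scen$waveforms$t < 0.6])
    }
    rows[[step + 1L]] <- row
    if (step == params$n_steps) break
    depth_cycle <- accumulate_cycle(cyc$pressures, cyc$slides, params)
    upd <- tryCatch(
      apply_wear_step(state, depth_cycle, scen$medial, params,
                      smoothing = isTRUE(scen$smoothing)),
      error = function(e)
        stop(sprintf("wear step %d: %s", step + 1L, conditionMessage(e)),
             call. = FALSE))
    state <- upd$state
    scen$medial <- upd$geom
    # cumulative figures belong to the *next* recorded state
  }
  history <- do.call(rbind, rows)
  state$history <- history
  list(state = state, medial = scen$medial, history = history,
       first_cycle = first_cycle, last_cycle = last_cycle)
}
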