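#' Archard wear parameters
#'
#' Constants of the linear (Archard) wear law \eqn{H = K_w \sigma S} and the
#' adaptive update schedule: wear factor \eqn{K_w} = 3.3e-7 mm^3/(N m) for
#' conventional UHMWPE against polished CoCrMo, polyethylene density
#' 0.93 mg/mm^3 for gravimetric conversion, and a 10-step schedule of 0.5
#' million cycles (MC) per step (5 MC total).
#'
#' @param wear_factor wear factor Kw (mm^3/(N m)), >= 0.
#' @param density polyethylene density (mg/mm^3), > 0.
#' @param cycles_per_step gait cycles represented by one geometry-update
#'   step.
#' @param n_steps number of update steps.
#' @return object of class \code{archard_params}.
#' @export
archard_params <- function(wear_factor = 3.3e-7, density = 0.93,
                           cycles_per_step = 5e5, n_steps = 10L) {
  stopifnot(wear_factor >= 0, density > 0, cycles_per_step > 0, n_steps >= 0)
  structure(list(wear_factor = wear_factor, density = density,
                 cycles_per_step = cycles_per_step,
                 n_steps = as.integer(n_steps)),
            class = "archard_params")
}

#' Archard linear wear depth
#'
#' \eqn{H = K_w \sigma S} with the unit contract Kw [mm^3/(N m)] x sigma
#' [MPa = N/mm^2] x S [m] giving depth in mm.
#'
#' @param pressure contact stress sigma (MPa), >= 0, vectorized.
#' @param slide sliding distance S (m), >= 0, vectorized.
#' @param params an \code{\link{archard_params}}.
#' @return wear depth (mm).
#' @export
archard_depth_increment <- function(pressure, slide,
                                    params = archard_params()) {
  if (any(pressure < 0)) stop("pressure must be >= 0", call. = FALSE)
  if (any(slide < 0)) stop("sliding distance must be >= 0", call. = FALSE)
  params$wear_factor * pressure * slide
}

#' Fresh wear state for a bearing surface
#'
#' @param geom the \code{\link{compartment_geometry}} whose bearing surface
#'   accumulates wear.
#' @return object of class \code{wear_state}: cumulative per-node depth
#'   (mm), volume loss (mm^3), mass loss (mg) and an empty step history.
#' @export
wear_state <- function(geom) {
  structure(list(depth = matrix(0, length(geom$tibial$x),
                                length(geom$tibial$z)),
                 volume_loss = 0, mass_loss = 0,
                 history = data.frame()),
            class = "wear_state")
}

#' @export
print.wear_state <- function(x, ...) {
  cat(sprintf("wear_state: %.2f mm^3 (%.2f mg) lost, max depth %.4f mm, %d steps\n",
              x$volume_loss, x$mass_loss, max(x$depth), nrow(x$history)))
  invisible(x)
}

#' Per-cycle nodal wear depth field
#'
#' Sums the Archard increments of one representative gait cycle: for every
#' bearing node, \eqn{\sum_i K_w\, p_i\, s_i} over the time increments, with
#' the pressure taken at the increment start and the sliding magnitude
#' across the increment. Nodes out of contact contribute nothing.
#'
#' @param pressures matrix nodes x samples of contact pressure (MPa).
#' @param slides matrix nodes x samples of sliding increments (mm), column i
#'   holding the slide from sample i to i+1 (the last column wraps to the
#'   first sample of the next cycle).
#' @param params an \code{\link{archard_params}}.
#' @return per-node depth for one cycle (mm), as a vector matching the rows.
#' @export
accumulate_cycle <- function(pressures, slides, params = archard_params()) {
  if (!all(dim(pressures) == dim(slides)))
    stop("pressure and slide fields disagree in shape across the cycle",
         call. = FALSE)
  rowSums(archard_depth_increment(pressures, slides / 1000, params))
}

# 5-point Laplacian smoothing of a nodal field (Neumann edges), blending
# `lambda` of the neighbour average into each node.
smooth_field <- function(f, lambda = 0.5, passes = 1L) {
  n <- nrow(f); m <- ncol(f)
  for (p in seq_len(passes)) {
    up <- f[c(1L, seq_len(n - 1L)), ]
    dn <- f[c(seq_len(n - 1L) + 1L, n), ]
    lf <- f[, c(1L, seq_len(m - 1L))]
    rt <- f[, c(seq_len(m - 1L) + 1L, m)]
    f <- (1 - lambda) * f + lambda * (up + dn + lf + rt) / 4
  }
  f
}

#' Apply one adaptive wear step to the bearing surface
#'
#' Scales the per-cycle depth field to the step's cycle count, recedes each
#' bearing node along its current outward surface normal (realized on the
#' height field as a height decrease of recession divided by the normal's
#' vertical component), and books the removed volume (recession times
#' surface nodal area) and mass (density times volume). Surface normals are
#' recomputed afterwards via the updated heights.
#'
#' @param state a \code{\link{wear_state}}.
#' @param cycle_depth per-node depth of one cycle (mm), matrix over the
#'   bearing lattice, >= 0.
#' @param geom the \code{\link{compartment_geometry}} being worn.
#' @param params an \code{\link{archard_params}}.
#' @param smoothing apply one Laplacian smoothing pass to the step's depth
#'   field before applying it (default FALSE).
#' @return list \code{state} (updated) and \code{geom} (receded surface).
#' @export
apply_wear_step <- function(state, cycle_depth, geom,
                            params = archard_params(), smoothing = FALSE) {
  cycle_depth <- matrix(cycle_depth, nrow(state$depth), ncol(state$depth))
  if (any(cycle_depth < 0))
    stop("cycle depth field must be >= 0", call. = FALSE)
  recession <- cycle_depth * params$cycles_per_step
  if (smoothing) recession <- smooth_field(recession)
  nz_vert <- surface_normals(geom$tibial)$ny
  dh <- recession / nz_vert
  if (any(geom$tibial$height - dh <= 0))
    stop("wear recession exhausts the insert thickness; simulation halted",
         call. = FALSE)
  dv <- sum(dh * geom$tibial$nodal_area)
  geom$tibial$height <- geom$tibial$height - dh
  state$depth <- state$depth + recession
  state$volume_loss <- state$volume_loss + dv
  state$mass_loss <- state$mass_loss + params$density * dv
  list(state = state, geom = geom)
}

#' Centroid of the worn region
#'
#' Depth-weighted centroid of the cumulative wear field in compartment-local
#' coordinates (x anterior +, z medial +).
#'
#' @param state a \code{\link{wear_state}}.
#' @param geom the worn \code{\link{compartment_geometry}}.
#' @return named vector \code{c(x, z)} (mm); NA if nothing has worn.
#' @export
wear_centroid <- function(state, geom) {
  w <- state$depth * geom$tibial$nodal_area
  tot <- sum(w)
  if (tot <= 0) return(c(x = NA_real_, z = NA_real_))
  X <- outer(geom$tibial$x, rep(1, length(geom$tibial$z)))
  Z <- outer(rep(1, length(geom$tibial$x)), geom$tibial$z)
  c(x = sum(w * X) / tot, z = sum(w * Z) / tot)
}

#' Triangulated volume of a height-field solid
#'
#' Volume enclosed between a height field and its base plane, integrated
#' over the piecewise-linear interpolant (two triangles per lattice cell).
#' Serves as the independent check on the wear loop's nodal volume
#' bookkeeping.
#'
#' @param grid a \code{surface_grid}.
#' @return volume (mm^3).
#' @export
heightfield_volume <- function(grid) {
  h <- grid$height
  n <- nrow(h); m <- ncol(h)
  dx <- grid$x[2L] - grid$x[1L]; dz <- grid$z[2L] - grid$z[1L]
  tri_area <- dx * dz / 2
  h00 <- h[-n, -m]; h10 <- h[-1L, -m]; h01 <- h[-n, -1L]; h11 <- h[-1L, -1L]
  sum((h00 + h10 + h01) / 3 * tri_area) +
    sum((h10 + h01 + h11) / 3 * tri_area)
}
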