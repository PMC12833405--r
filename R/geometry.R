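#' Circular-arc sagitta
#'
#' Height drop of a circular arc of radius \code{radius} at lateral offset
#' \code{r} from its apex: \eqn{R - \sqrt{R^2 - r^2}}.
#'
#' @param r numeric vector of offsets from the apex (mm).
#' @param radius arc radius (mm), positive.
#' @return numeric vector of drops (mm), zero at \code{r = 0}.
#' @export
sagitta <- function(r, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number", call. = FALSE)
  if (any(abs(r) > radius))
    stop("footprint half-extent exceeds articular radius ", radius, " mm",
         call. = FALSE)
  radius - sqrt(radius^2 - r^2)
}

#' Implant dimensional specification
#'
#' Dimensions of a fixed-bearing medial unicompartmental prosthesis:
#' femoral-component footprint, polyethylene insert footprint and thickness,
#' and the sagittal/coronal articular radii of both surfaces. Footprint
#' defaults follow the ISO 7207-1 style nominal sizes of a small medial
#' component (femoral 45 x 20 mm AP x ML; insert 41 x 26 mm; 8 mm thick).
#' Articular radii are representative of a low-conformity fixed-bearing
#' design; the insert radii must be at least the femoral radii (non-negative
#' clearance, conformity ratio <= 1).
#'
#' @param femoral_ml_width,femoral_ap_length femoral footprint (mm).
#' @param insert_ml,insert_ap insert footprint (mm).
#' @param insert_thickness insert material thickness at the dish bottom (mm).
#' @param femoral_sagittal_radius,femoral_coronal_radius femoral articular
#'   radii (mm).
#' @param insert_sagittal_radius,insert_coronal_radius insert dish radii (mm).
#' @return object of class \code{implant_spec}.
#' @export
implant_spec <- function(femoral_ml_width = 20, femoral_ap_length = 45,
                         insert_ml = 26, insert_ap = 41,
                         insert_thickness = 8,
                         femoral_sagittal_radius = 28,
                         femoral_coronal_radius = 22,
                         insert_sagittal_radius = 45,
                         insert_coronal_radius = 30) {
  spec <- list(femoral_ml_width = femoral_ml_width,
               femoral_ap_length = femoral_ap_length,
               insert_ml = insert_ml, insert_ap = insert_ap,
               insert_thickness = insert_thickness,
               femoral_sagittal_radius = femoral_sagittal_radius,
               femoral_coronal_radius = femoral_coronal_radius,
               insert_sagittal_radius = insert_sagittal_radius,
               insert_coronal_radius = insert_coronal_radius)
  if (any(vapply(spec, function(v) !is.numeric(v) || length(v) != 1L ||
                   !is.finite(v) || v <= 0, logical(1L))))
    stop("all implant dimensions must be single positive numbers",
         call. = FALSE)
  if (insert_sagittal_radius < femoral_sagittal_radius ||
      insert_coronal_radius < femoral_coronal_radius)
    stop("insert radii must be >= femoral radii (conformity ratio <= 1)",
         call. = FALSE)
  structure(spec, class = "implant_spec")
}

# Uniform lattice over [-L/2, L/2] with approximately `resolution` nodes/mm.
grid_axis <- function(length_mm, resolution) {
  n_int <- max(1L, as.integer(round(length_mm * resolution)))
  seq(-length_mm / 2, length_mm / 2, length.out = n_int + 1L)
}

# Trapezoid quadrature weights for a uniform axis (half cells at the ends);
# weights sum exactly to the axis span.
axis_weights <- function(x) {
  n <- length(x)
  dx <- (x[n] - x[1]) / (n - 1L)
  w <- rep(dx, n)
  w[c(1L, n)] <- dx / 2
  w
}

#' Regular-grid height-field surface
#'
#' The shared surface representation for the femoral component, the insert
#' and the lateral tibial cartilage: a rectangular lattice in the transverse
#' plane (x = anterior +, z = medial +, mm) carrying a height per node
#' (articular direction, + proximal), a trapezoid nodal area and an outward
#' unit normal. Heights are stored column-per-z so \code{height[i, j]}
#' corresponds to \code{(x[i], z[j])}.
#'
#' @param x,z strictly increasing, uniformly spaced lattice axes (mm).
#' @param height numeric matrix \code{length(x)} x \code{length(z)} (mm).
#' @param footprint optional \code{c(ap_length, ml_width)}; defaults to the
#'   axis spans.
#' @param analytic optional list describing an analytic generator of the
#'   height field (kept so that femoral heights can be evaluated exactly at
#'   arbitrary in-plane positions).
#' @return object of class \code{surface_grid}.
#' @export
surface_grid <- function(x, z, height, footprint = NULL, analytic = NULL) {
  stopifnot(is.numeric(x), is.numeric(z), length(x) >= 2L, length(z) >= 2L)
  for (ax in list(x, z)) {
    d <- diff(ax)
    if (any(d <= 0) || diff(range(d)) > 1e-9 * max(d))
      stop("lattice axes must be strictly increasing and uniformly spaced",
           call. = FALSE)
  }
  height <- as.matrix(height)
  if (nrow(height) != length(x) || ncol(height) != length(z))
    stop("height matrix must be length(x) x length(z)", call. = FALSE)
  if (is.null(footprint)) footprint <- c(diff(range(x)), diff(range(z)))
  area <- outer(axis_weights(x), axis_weights(z))
  structure(list(x = x, z = z, height = height, nodal_area = area,
                 footprint = c(ap_length = footprint[[1L]],
                               ml_width = footprint[[2L]]),
                 analytic = analytic),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("surface_grid: %d x %d nodes, footprint %.1f x %.1f mm (AP x ML)\n",
              length(x$x), length(x$z), x$footprint[1L], x$footprint[2L]))
  cat(sprintf("  height range [%.3f, %.3f] mm, total nodal area %.2f mm^2\n",
              min(x$height), max(x$height), sum(x$nodal_area)))
  invisible(x)
}

#' Outward unit normals of a height-field surface
#'
#' Normals of the graph \eqn{y = h(x, z)} computed from central-difference
#' gradients, \eqn{n = (-h_x, 1, -h_z)/\|\cdot\|} with the middle component
#' along the proximal (+height) direction.
#'
#' @param grid a \code{surface_grid}.
#' @return list of matrices \code{nx}, \code{ny}, \code{nz} (components along
#'   x, height and z); each normal has unit length.
#' @export
surface_normals <- function(grid) {
  h <- grid$height
  dx <- grid$x[2L] - grid$x[1L]
  dz <- grid$z[2L] - grid$z[1L]
  hx <- h; hz <- h
  n <- nrow(h); m <- ncol(h)
  hx[2:(n - 1L), ] <- (h[3:n, ] - h[1:(n - 2L), ]) / (2 * dx)
  hx[1L, ] <- (h[2L, ] - h[1L, ]) / dx
  hx[n, ] <- (h[n, ] - h[n - 1L, ]) / dx
  hz[, 2:(m - 1L)] <- (h[, 3:m] - h[, 1:(m - 2L)]) / (2 * dz)
  hz[, 1L] <- (h[, 2L] - h[, 1L]) / dz
  hz[, m] <- (h[, m] - h[, m - 1L]) / dz
  nrm <- sqrt(1 + hx^2 + hz^2)
  list(nx = -hx / nrm, ny = 1 / nrm, nz = -hz / nrm)
}

check_resolution <- function(x, z) {
  if (length(x) < 20L || length(z) < 20L)
    stop("resolution too coarse: fewer than 20 nodes along one axis",
         call. = FALSE)
}

#' Biconvex femoral articular surface
#'
#' Height field of the femoral component's articulating condyle over its
#' footprint, a spherical-arc (torus-like) idealization:
#' \deqn{h(x, z) = h_0 - (R_s - \sqrt{R_s^2 - x^2}) - (R_c - \sqrt{R_c^2 - z^2})}
#' with sagittal radius \eqn{R_s} along x (AP) and coronal radius \eqn{R_c}
#' along z (ML). The apex sits at the footprint centre with height \eqn{h_0}.
#' The analytic generator is retained so the rigid femoral surface can be
#' evaluated exactly at translated in-plane positions during contact solves.
#'
#' @param spec an \code{\link{implant_spec}}.
#' @param resolution lattice density (nodes per mm), default 1.
#' @param h0 apex height (mm), default 0.
#' @return a \code{surface_grid}.
#' @export
make_femoral_surface <- function(spec, resolution = 1, h0 = 0) {
  stopifnot(inherits(spec, "implant_spec"))
  x <- grid_axis(spec$femoral_ap_length, resolution)
  z <- grid_axis(spec$femoral_ml_width, resolution)
  check_resolution(x, z)
  rs <- spec$femoral_sagittal_radius
  rc <- spec$femoral_coronal_radius
  h <- h0 - outer(sagitta(x, rs), rep(1, length(z))) -
    outer(rep(1, length(x)), sagitta(z, rc))
  surface_grid(x, z, h,
               footprint = c(spec$femoral_ap_length, spec$femoral_ml_width),
               analytic = list(kind = "femoral", h0 = h0,
                               sagittal_radius = rs, coronal_radius = rc,
                               half_ap = spec$femoral_ap_length / 2,
                               half_ml = spec$femoral_ml_width / 2))
}

#' Dished polyethylene insert surface
#'
#' Height field of the insert's articular dish measured above the baseplate:
#' the material thickness equals \code{insert_thickness} at the dish bottom
#' and grows with the dish sagitta away from it,
#' \deqn{h(x, z) = t + (R_s - \sqrt{R_s^2 - x^2}) + (R_c - \sqrt{R_c^2 - z^2}).}
#' The stored height doubles as the remaining local material thickness, which
#' the wear loop depletes.
#'
#' @inheritParams make_femoral_surface
#' @return a \code{surface_grid}.
#' @export
make_insert_surface <- function(spec, resolution = 1) {
  stopifnot(inherits(spec, "implant_spec"))
  x <- grid_axis(spec$insert_ap, resolution)
  z <- grid_axis(spec$insert_ml, resolution)
  check_resolution(x, z)
  rs <- spec$insert_sagittal_radius
  rc <- spec$insert_coronal_radius
  h <- spec$insert_thickness +
    outer(sagitta(x, rs), rep(1, length(z))) +
    outer(rep(1, length(x)), sagitta(z, rc))
  surface_grid(x, z, h,
               footprint = c(spec$insert_ap, spec$insert_ml),
               analytic = list(kind = "dish", base = spec$insert_thickness,
                               sagittal_radius = rs, coronal_radius = rc))
}

#' Articulating compartment (femoral surface over a deformable tibial layer)
#'
#' Pairs a rigid femoral surface with a tibial bearing surface (polyethylene
#' insert or lateral cartilage) backed by an elastic-foundation layer of
#' thickness \code{layer_thickness}. \code{center_z} places the compartment
#' centre in joint (whole-knee) mediolateral coordinates; \code{datum} is an
#' additive joint-frame offset of the tibial surface used when balancing the
#' two compartments of a whole-joint model.
#'
#' @param femoral_surface,tibial_surface \code{surface_grid} objects.
#' @param layer_thickness deformable-layer thickness (mm).
#' @param label \code{"medial_implant"} or \code{"lateral_cartilage"}.
#' @param center_z compartment centre, joint ML coordinate (mm, medial +).
#' @param datum joint-frame vertical offset of the tibial surface (mm).
#' @return object of class \code{compartment_geometry}.
#' @export
compartment_geometry <- function(femoral_surface, tibial_surface,
                                 layer_thickness,
                                 label = c("medial_implant",
                                           "lateral_cartilage"),
                                 center_z = 0, datum = 0) {
  stopifnot(inherits(femoral_surface, "surface_grid"),
            inherits(tibial_surface, "surface_grid"),
            layer_thickness > 0)
  label <- match.arg(label)
  dxf <- femoral_surface$x[2L] - femoral_surface$x[1L]
  dxt <- tibial_surface$x[2L] - tibial_surface$x[1L]
  if (abs(dxf - dxt) > 1e-9)
    stop("femoral and tibial grids must share lattice resolution",
         call. = FALSE)
  structure(list(femoral = femoral_surface, tibial = tibial_surface,
                 layer_thickness = layer_thickness, label = label,
                 center_z = center_z, datum = datum),
            class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("compartment_geometry (%s): center_z = %.1f mm, layer %.1f mm\n",
              x$label, x$center_z, x$layer_thickness))
  print(x$tibial)
  invisible(x)
}

#' Default lateral-compartment configuration
#'
#' Parameters of the synthetic lateral tibiofemoral compartment: a shallow
#' cartilage dish facing a lateral femoral condyle of the same radii class as
#' the implant condyle. The deformable layer lumps the tibial/femoral
#' cartilage thickness with an effective meniscus contribution (the meniscus
#' itself is not modelled as a continuum).
#'
#' @param ap_length,ml_width lateral contact footprint (mm).
#' @param femoral_sagittal_radius,femoral_coronal_radius lateral condyle
#'   radii (mm).
#' @param dish_sagittal_radius,dish_coronal_radius cartilage dish radii (mm).
#' @param cartilage_thickness combined articular cartilage thickness (mm).
#' @param meniscus_effective_thickness effective meniscus contribution to the
#'   deformable layer (mm); zero removes it.
#' @return named list of lateral-compartment parameters.
#' @export
lateral_config <- function(ap_length = 38, ml_width = 28,
                           femoral_sagittal_radius = 28,
                           femoral_coronal_radius = 22,
                           dish_sagittal_radius = 70,
                           dish_coronal_radius = 55,
                           cartilage_thickness = 4,
                           meniscus_effective_thickness = 4) {
  list(ap_length = ap_length, ml_width = ml_width,
       femoral_sagittal_radius = femoral_sagittal_radius,
       femoral_coronal_radius = femoral_coronal_radius,
       dish_sagittal_radius = dish_sagittal_radius,
       dish_coronal_radius = dish_coronal_radius,
       cartilage_thickness = cartilage_thickness,
       meniscus_effective_thickness = meniscus_effective_thickness)
}

#' Synthetic lateral cartilage compartment
#'
#' Builds the lateral tibial cartilage surface (a shallow dish) together with
#' a matching lateral femoral condyle as a \code{compartment_geometry}. The
#' foundation layer thickness is the cartilage thickness plus the effective
#' meniscus contribution.
#'
#' @param config list as returned by \code{\link{lateral_config}}.
#' @param resolution lattice density (nodes per mm), default 1.
#' @param center_z joint ML coordinate of the compartment centre (mm,
#'   negative = lateral), default -25.
#' @return a \code{compartment_geometry} with label
#'   \code{"lateral_cartilage"}.
#' @export
make_lateral_cartilage_surface <- function(config = lateral_config(),
                                           resolution = 1, center_z = -25) {
  stopifnot(config$cartilage_thickness > 0,
            config$meniscus_effective_thickness >= 0)
  spec_like <- implant_spec(femoral_ml_width = config$ml_width,
                            femoral_ap_length = config$ap_length,
                            insert_ml = config$ml_width,
                            insert_ap = config$ap_length,
                            insert_thickness = config$cartilage_thickness,
                            femoral_sagittal_radius =
                              config$femoral_sagittal_radius,
                            femoral_coronal_radius =
                              config$femoral_coronal_radius,
                            insert_sagittal_radius =
                              config$dish_sagittal_radius,
                            insert_coronal_radius =
                              config$dish_coronal_radius)
  fem <- make_femoral_surface(spec_like, resolution)
  dish <- make_insert_surface(spec_like, resolution)
  compartment_geometry(fem, dish,
                       layer_thickness = config$cartilage_thickness +
                         config$meniscus_effective_thickness,
                       label = "lateral_cartilage", center_z = center_z)
}

#' Medial implant compartment
#'
#' Femoral component over the polyethylene insert as a
#' \code{compartment_geometry}; the foundation layer is the insert thickness.
#'
#' @param spec an \code{\link{implant_spec}}.
#' @param resolution lattice density (nodes per mm).
#' @param center_z joint ML coordinate of the compartment centre (mm,
#'   positive = medial), default 25.
#' @return a \code{compartment_geometry} with label \code{"medial_implant"}.
#' @export
make_medial_compartment <- function(spec = implant_spec(), resolution = 1,
                                    center_z = 25) {
  compartment_geometry(make_femoral_surface(spec, resolution),
                       make_insert_surface(spec, resolution),
                       layer_thickness = spec$insert_thickness,
                       label = "medial_implant", center_z = center_z)
}

# Exact femoral height drop below the apex at in-plane offsets (x, z) from
# the component centre; Inf outside the component footprint (no contact).
femoral_drop <- function(femoral_surface, x, z) {
  a <- femoral_surface$analytic
  if (is.null(a) || a$kind != "femoral")
    stop("femoral surface lacks its analytic generator", call. = FALSE)
  X <- outer(x, rep(1, length(z)))
  Z <- outer(rep(1, length(x)), z)
  drop <- matrix(Inf, length(x), length(z))
  inside <- abs(X) <= a$half_ap & abs(Z) <= a$half_ml &
    abs(X) <= a$sagittal_radius & abs(Z) <= a$coronal_radius
  drop[inside] <- (a$sagittal_radius - sqrt(a$sagittal_radius^2 - X[inside]^2)) +
    (a$coronal_radius - sqrt(a$coronal_radius^2 - Z[inside]^2))
  drop
}
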