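#' @title Synthetic LV geometry
#' @description Truncated prolate-spheroid LV surfaces with a well-defined
#'   apex (minimum long-axis coordinate) and a basal cutting plane normal to
#'   the long axis.  The long axis is z; the apex sits at z = -a and the
#'   base plane at z = -a*cos(base angle).  Azimuth phi is measured from +x
#'   counterclockwise.
#' @name lv-geometry
NULL

# Surface point for parameter (theta from apex, phi); axes = c(a, bx, by).
# radial_mod(theta, phi) optionally scales the short-axis (x, y) components,
# used for end-systolic shapes with locally reduced contraction in scar.
spheroid_points <- function(theta, phi, axes, radial_mod = NULL) {
  s <- sin(theta)
  m <- if (is.null(radial_mod)) 1 else radial_mod(theta, phi)
  cbind(axes[2] * s * cos(phi) * m,
        axes[3] * s * sin(phi) * m,
        -axes[1] * cos(theta))
}

# Triangulated truncated spheroid: pole vertex at the apex plus n_theta
# rings of n_phi vertices, quads split into triangles, outward orientation.
build_spheroid_mesh <- function(axes, base_angle_deg, n_theta, n_phi,
                                radial_mod = NULL) {
  th_base <- base_angle_deg * pi / 180
  th <- seq(0, th_base, length.out = n_theta + 1)[-1]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid <- expand.grid(phi = ph, theta = th)
  verts <- rbind(c(0, 0, -axes[1]),
                 spheroid_points(grid$theta, grid$phi, axes, radial_mod))
  vid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- matrix(0L, 0, 3)
  jj <- seq_len(n_phi)
  # apex fan: outward normals need (pole, j+1, j) winding with z down at apex
  faces <- rbind(faces, cbind(1L, vid(1L, jj + 1L), vid(1L, jj)))
  for (i in seq_len(n_theta - 1L)) {
    a <- vid(i, jj)
    b <- vid(i, jj + 1L)
    c <- vid(i + 1L, jj + 1L)
    d <- vid(i + 1L, jj)
    faces <- rbind(faces, cbind(a, c, b), cbind(a, d, c))
  }
  base_z <- -axes[1] * cos(th_base)
  surface_mesh(verts, faces,
               apex_vertex = 1L,
               base_plane = list(point = c(0, 0, base_z), normal = c(0, 0, 1)))
}

# closed planar contour polygon of the surface at height z (n points)
spheroid_contour <- function(z, axes, n = 120, radial_mod = NULL) {
  u <- -z / axes[1]
  if (abs(u) >= 1) stop("geometry error: slice outside the surface")
  theta <- acos(u)
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- spheroid_points(rep(theta, n), phi, axes, radial_mod)
  p[, 1:2, drop = FALSE]
}

#' Generate synthetic LV geometry for one subject
#'
#' Builds closed (up to the base plane) triangulated endocardial and
#' epicardial surfaces at end-diastole and end-systole, plus a short-axis
#' contour stack consistent with the meshes.  The slice stack stops
#' `basal_gap_mm` short of the base plane, emulating incomplete basal MRI
#' coverage.  If a `scar_field` is supplied, end-systolic endocardial
#' contraction is locally reduced in scar (akinesis), consistently in the
#' ES mesh and ES contours.
#'
#' @param config [lv_config()].
#' @param subject_seed integer seed for this subject's stochastic draws.
#' @param scar_field optional scar field (see [generate_scar_field()]) used
#'   to modulate end-systolic contraction.
#' @return list with `endo_mesh_ed`, `endo_mesh_es`, `epi_mesh_ed`,
#'   `epi_mesh_es` (class `surface_mesh`), `slice_stack` (class
#'   `contour_stack`) and `params` (realized subject axes).
#' @export
generate_lv_geometry <- function(config, subject_seed, scar_field = NULL) {
  stopifnot(inherits(config, "lv_config"))
  set.seed(derive_seed(subject_seed, 11))
  scl <- exp(stats::rnorm(1, 0, config$subject_scale_sd))
  a <- config$endo_long_axis_mm * scl
  bx <- config$endo_short_axis_mm[1] * scl
  by <- config$endo_short_axis_mm[2] * scl
  t_ed <- config$wall_thickness_ed_mm
  t_es <- t_ed + config$wall_thickening_mm
  ax_endo_ed <- c(a, bx, by)
  ax_epi_ed <- ax_endo_ed + t_ed
  ax_endo_es <- c(a * config$es_long_axis_scale,
                  bx * config$es_short_axis_scale,
                  by * config$es_short_axis_scale)
  ax_epi_es <- ax_endo_es + t_es

  es_mod <- NULL
  if (!is.null(scar_field) && config$scar_akinesis_factor > 0) {
    k <- config$scar_akinesis_factor
    es_mod <- function(theta, phi) {
      # evaluate transmurality at the matching ED endocardial location
      p_ed <- spheroid_points(theta, phi, ax_endo_ed)
      tm <- tm_field_eval(scar_field, p_ed) / 100
      1 + k * tm * (1 / config$es_short_axis_scale - 1)
    }
  }

  nt <- config$n_theta
  np <- config$n_phi
  ba <- config$base_angle_deg
  endo_ed <- build_spheroid_mesh(ax_endo_ed, ba, nt, np)
  endo_es <- build_spheroid_mesh(ax_endo_es, ba, nt, np, radial_mod = es_mod)
  epi_ed <- build_spheroid_mesh(ax_epi_ed, ba, nt, np)
  epi_es <- build_spheroid_mesh(ax_epi_es, ba, nt, np)

  base_z <- -a * cos(ba * pi / 180)
  z_top <- base_z - config$basal_gap_mm
  # slab centers tile the long axis from half a thickness above the apex
  # up to the basal coverage limit
  zs <- seq(-a + 0.5 * config$slice_thickness_mm, z_top,
            by = config$slice_thickness_mm)
  slices <- lapply(zs, function(z) {
    list(z = z,
         endo_ed = spheroid_contour(z, ax_endo_ed),
         epi_ed = spheroid_contour(z, ax_epi_ed),
         endo_es = spheroid_contour(z, ax_endo_es, radial_mod = es_mod),
         epi_es = spheroid_contour(z, ax_epi_es))
  })
  stack <- structure(list(slices = slices, axis = c(0, 0, 1),
                          slice_thickness_mm = config$slice_thickness_mm),
                     class = "contour_stack")
  list(endo_mesh_ed = endo_ed, endo_mesh_es = endo_es,
       epi_mesh_ed = epi_ed, epi_mesh_es = epi_es,
       slice_stack = stack,
       params = list(scale = scl, ax_endo_ed = ax_endo_ed,
                     ax_epi_ed = ax_epi_ed, ax_endo_es = ax_endo_es,
                     ax_epi_es = ax_epi_es, base_z = base_z,
                     wall_thickness_ed = t_ed, wall_thickness_es = t_es))
}

#' @export
print.contour_stack <- function(x, ...) {
  zs <- vapply(x$slices, function(s) s$z, 0)
  cat(sprintf("contour_stack: %d slices, z from %.1f to %.1f mm\n",
              length(zs), min(zs), max(zs)))
  invisible(x)
}

# truncated-normal draws by inverse-CDF; exact, vectorized
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}
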