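#' Generate a per-vertex scar transmurality field
#'
#' Places a contiguous, mostly transmural scar patch on the endocardial
#' mesh at the configured apicoseptal location: transmurality is 100% in a
#' core, ramps linearly to 0 over `border_zone_width_mm`, and the core
#' radius is calibrated on the mesh so that the surface fraction with
#' transmurality >= 50% matches the subject's target fraction (drawn around
#' `scar_surface_fraction`).
#'
#' @param endo_mesh endocardial `surface_mesh` (end-diastole).
#' @param config [lv_config()].
#' @param subject_seed subject seed.
#' @return object of class `scar_field`: list with `tm` (per-vertex
#'   transmurality %), `center` (3-D scar centre), `r_core`, `border_mm`
#'   and `fraction_target`.
#' @export
generate_scar_field <- function(endo_mesh, config, subject_seed) {
  stopifnot(inherits(config, "lv_config"))
  if (config$scar_surface_fraction >= 1)
    stop("configuration error: scar_surface_fraction must be < 1")
  nv <- nrow(endo_mesh$vertices)
  if (config$scar_surface_fraction <= 0) {
    return(structure(list(tm = numeric(nv), center = c(NA, NA, NA),
                          r_core = 0, border_mm = config$border_zone_width_mm,
                          fraction_target = 0),
                     class = "scar_field"))
  }
  set.seed(derive_seed(subject_seed, 23))
  frac <- rtrunc_norm(1, config$scar_surface_fraction, config$scar_fraction_sd,
                      lower = 0.03, upper = 0.6)
  th_c <- (config$scar_center_theta_deg +
             stats::rnorm(1, 0, config$scar_center_jitter_deg)) * pi / 180
  ph_c <- (config$scar_center_phi_deg +
             stats::rnorm(1, 0, config$scar_center_jitter_deg)) * pi / 180
  # pick the mesh vertex closest in direction to the configured centre
  # (uniform subject scaling preserves directions)
  axes <- c(config$endo_long_axis_mm, config$endo_short_axis_mm)
  dir_c <- spheroid_points(th_c, ph_c, axes)
  dir_c <- dir_c / sqrt(sum(dir_c^2))
  vdir <- endo_mesh$vertices / sqrt(rowSums(endo_mesh$vertices^2))
  center <- endo_mesh$vertices[which.max(vdir %*% t(dir_c)), ]

  d <- sqrt(rowSums(sweep(endo_mesh$vertices, 2, center)^2))
  va <- mesh_vertex_areas(endo_mesh)
  o <- order(d)
  cum <- cumsum(va[o]) / sum(va)
  r50 <- d[o][which(cum >= frac)[1]]
  border <- config$border_zone_width_mm
  r_core <- max(r50 - border / 2, 0.5)
  field <- structure(list(tm = NULL, center = center, r_core = r_core,
                          border_mm = border, fraction_target = frac),
                     class = "scar_field")
  field$tm <- tm_field_eval(field, endo_mesh$vertices)
  field
}

#' Evaluate a scar transmurality field at arbitrary 3-D points
#' @param field `scar_field`.
#' @param points n x 3 positions (mm).
#' @return transmurality % in \[0, 100\].
#' @export
tm_field_eval <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (field$fraction_target <= 0 || anyNA(field$center))
    return(numeric(nrow(points)))
  d <- sqrt(rowSums(sweep(points, 2, field$center)^2))
  100 * pmin(1, pmax(0, (field$r_core + field$border_mm - d) / field$border_mm))
}

#' Sample a synthetic EMM point cloud on the endocardium
#'
#' Points are sampled uniformly by surface area over the full endocardial
#' mesh (including the basal band not covered by the MRI slice stack).
#' Each point's UV/BV/LLS/LAT values are drawn from the healthy or scar
#' class-conditional distribution according to the local true transmurality
#' (scar when TM >= 50%), evaluated at the pre-perturbation location.  The
#' cloud is then rigidly perturbed by a random misalignment (rotation <=
#' `misalignment_rot_deg_max`) plus isotropic positional noise.
#'
#' @param endo_mesh endocardial `surface_mesh`.
#' @param scar_field `scar_field` on that mesh.
#' @param config [lv_config()].
#' @param subject_seed subject seed.
#' @param subject_id subject label stored with the points.
#' @return list with `emm` (class `emm_map`) and `truth` (true transform,
#'   clean positions, per-point transmurality and scar labels).
#' @export
sample_emm_map <- function(endo_mesh, scar_field, config, subject_seed,
                           subject_id = subject_seed) {
  if (nrow(endo_mesh$faces) == 0) stop("geometry error: empty mesh")
  set.seed(derive_seed(subject_seed, 37))
  n <- max(config$points_min,
           round(stats::rnorm(1, config$points_mean, config$points_sd)))
  smp <- sample_mesh_surface(endo_mesh, n)
  tm <- tm_field_eval(scar_field, smp$points)
  scar <- tm >= 50
  ep <- config$emm_params
  draw <- function(par, lower = -Inf) {
    row <- ep[ep$param == par, ]
    m <- ifelse(scar, row$scar_mean, row$healthy_mean)
    s <- ifelse(scar, row$scar_sd, row$healthy_sd)
    rtrunc_norm(n, m, s, lower = lower)
  }
  uv <- draw("uv", lower = 0)
  bv <- draw("bv", lower = 0)
  lls <- draw("lls")
  lat <- draw("lat")
  tf <- random_rigid_transform(config$misalignment_rot_deg_max,
                               config$misalignment_trans_mm)
  noise <- matrix(stats::rnorm(3 * n, 0, config$noise_sd_mm), ncol = 3)
  pos <- apply_transform(tf, smp$points) + noise
  emm <- structure(list(
    subject_id = subject_id,
    points = data.frame(subject_id = subject_id,
                        x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                        uv_mv = uv, bv_mv = bv, lls_pct = lls, lat_ms = lat)),
    class = "emm_map")
  truth <- list(true_transform = tf, clean_points = smp$points,
                tm_pct = tm, scar_label = as.integer(scar))
  list(emm = emm, truth = truth)
}

#' Positions of an EMM map as a matrix
#' @param emm `emm_map` (or a data.frame with `x_mm`, `y_mm`, `z_mm`).
#' @export
emm_positions <- function(emm) {
  pts <- if (inherits(emm, "emm_map")) emm$points else emm
  as.matrix(pts[, c("x_mm", "y_mm", "z_mm")])
}

#' @export
print.emm_map <- function(x, ...) {
  cat(sprintf("emm_map: subject %s, %d points\n", x$subject_id, nrow(x$points)))
  invisible(x)
}

# shortening waveform: zero baseline, linear ramp from (t0, 0) blended by a
# C1 quadratic into the peak (tp, amplitude), then slow linear recovery.
# The linear onset makes the steepest-slope tangent pass exactly through
# (t0, 0), so the tangent onset estimator is exact on noiseless curves.
strain_curve_eval <- function(t, amplitude, t0, tp, blend = 0.15,
                              recovery = 0.5) {
  s <- numeric(length(t))
  if (tp <= t0) tp <- t0 + 1
  tau <- (t - t0) / (tp - t0)
  m <- 1 / (1 - blend)
  tau1 <- 1 - 2 * blend
  ramp <- tau > 0 & tau <= tau1
  s[ramp] <- m * tau[ramp]
  top <- tau > tau1 & tau <= 1
  dtau <- tau[top] - tau1
  s[top] <- m * tau1 + m * dtau - m * dtau^2 / (4 * blend)
  tend <- max(t)
  after <- t > tp
  if (tend > tp)
    s[after] <- 1 - recovery * (t[after] - tp) / (tend - tp)
  amplitude * s
}

#' Generate synthetic circumferential strain curves
#'
#' One smooth unimodal shortening trace per slice and per 48-sector wedge.
#' Sector peak amplitudes are drawn so healthy and (non-akinetic) scar
#' sector medians match the configured medians; a configured fraction of
#' scar sectors is generated near-akinetic (peak shortening magnitude below
#' 7.5%).  Onset and peak times are snapped to the frame grid and recorded
#' as ground truth.
#'
#' @param slice_stack `contour_stack` from [generate_lv_geometry()].
#' @param scar_field `scar_field`.
#' @param config [lv_config()].
#' @param subject_seed subject seed.
#' @param subject_id subject label.
#' @return list with `curves` (long data.frame: subject, slice_index,
#'   sector_index, frame, time_ms, strain_pct) and `truth` (per-sector
#'   scar flag, amplitude, onset and peak times).
#' @export
generate_strain_curves <- function(slice_stack, scar_field, config,
                                   subject_seed, subject_id = subject_seed) {
  if (config$n_frames < 3)
    stop("configuration error: at least 3 time samples are required")
  set.seed(derive_seed(subject_seed, 53))
  times <- seq(0, config$cycle_ms, length.out = config$n_frames)
  snap <- function(t) times[pmin(length(times), pmax(1, round(t / times[2]) + 1))]
  ns <- config$n_sectors_strain
  phic <- (seq_len(ns) - 0.5) * 2 * pi / ns
  curves <- vector("list", length(slice_stack$slices))
  truth <- vector("list", length(slice_stack$slices))
  for (si in seq_along(slice_stack$slices)) {
    sl <- slice_stack$slices[[si]]
    ctr <- polygon_centroid(sl$endo_ed)
    re <- polygon_radius(sl$endo_ed, ctr, phic)
    pts <- cbind(ctr[1] + re * cos(phic), ctr[2] + re * sin(phic), sl$z)
    tm <- tm_field_eval(scar_field, pts)
    scar <- tm >= 50
    akin <- scar & stats::runif(ns) < config$akinetic_scar_fraction
    amp <- numeric(ns)
    thr <- config$akinetic_threshold_pct
    amp[akin] <- stats::runif(sum(akin), thr + 0.1, -1.5)
    ns_scar <- scar & !akin
    amp[ns_scar] <- rtrunc_norm(sum(ns_scar), config$strain_scar_median_pct,
                                config$strain_scar_sd, upper = thr)
    amp[!scar] <- rtrunc_norm(sum(!scar), config$strain_healthy_median_pct,
                              config$strain_healthy_sd, upper = thr)
    t0 <- snap(config$onset_healthy_ms + scar * config$onset_scar_delay_ms +
                 stats::rnorm(ns, 0, config$onset_jitter_ms))
    tp <- snap(config$peak_healthy_ms + scar * config$onset_scar_delay_ms +
                 stats::rnorm(ns, 0, config$peak_jitter_ms))
    tp <- pmax(tp, t0 + 3 * times[2])
    mat <- vapply(seq_len(ns),
                  function(j) strain_curve_eval(times, amp[j], t0[j], tp[j]),
                  numeric(length(times)))
    curves[[si]] <- data.frame(
      subject_id = subject_id, slice_index = si,
      sector_index = rep(0:(ns - 1), each = length(times)),
      frame = rep(seq_along(times), ns) - 1L,
      time_ms = rep(times, ns), strain_pct = as.vector(mat))
    truth[[si]] <- data.frame(subject_id = subject_id, slice_index = si,
                              sector_index = 0:(ns - 1), scar = scar,
                              tm_pct = tm, amplitude_pct = amp,
                              t0_ms = t0, tp_ms = tp, akinetic = akin)
  }
  list(curves = do.call(rbind, curves), truth = do.call(rbind, truth))
}

#' Generate synthetic LGE short-axis slices
#'
#' Per-slice myocardial intensity images: remote myocardium at baseline
#' intensity, hyperenhancement (`lge_enhancement` x remote, >= 2x) over the
#' transmural extent implied by the scar field (sub-endocardial inward
#' growth up to the local transmurality fraction of the wall), plus
#' additive Gaussian noise.  The pixel-level scar truth is retained.
#'
#' @param slice_stack `contour_stack`.
#' @param scar_field `scar_field`.
#' @param config [lv_config()].
#' @param subject_seed subject seed.
#' @return list of `lge_slice` objects.
#' @export
generate_lge_slices <- function(slice_stack, scar_field, config, subject_seed) {
  if (config$lge_pixel_mm <= 0)
    stop("configuration error: pixel spacing must be positive")
  set.seed(derive_seed(subject_seed, 67))
  px <- config$lge_pixel_mm
  lapply(seq_along(slice_stack$slices), function(si) {
    sl <- slice_stack$slices[[si]]
    epi <- sl$epi_ed
    xs <- seq(min(epi[, 1]) - 2 * px, max(epi[, 1]) + 2 * px, by = px)
    ys <- seq(min(epi[, 2]) - 2 * px, max(epi[, 2]) + 2 * px, by = px)
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    ctr <- polygon_centroid(sl$endo_ed)
    r <- sqrt((gx - ctr[1])^2 + (gy - ctr[2])^2)
    phi <- atan2(gy - ctr[2], gx - ctr[1])
    re <- polygon_radius(sl$endo_ed, ctr, phi)
    rp <- polygon_radius(sl$epi_ed, ctr, phi)
    myo <- r >= re & r <= rp
    endo_pts <- cbind(ctr[1] + re * cos(phi), ctr[2] + re * sin(phi), sl$z)
    frac <- tm_field_eval(scar_field, endo_pts) / 100
    scar <- myo & frac > 0 & r <= re + frac * (rp - re)
    base <- config$lge_remote_intensity
    inten <- ifelse(myo, base * (1 + (config$lge_enhancement - 1) * scar), 0)
    inten <- inten + stats::rnorm(length(inten), 0, config$lge_noise_sd)
    structure(list(
      intensity = matrix(inten, nrow = length(xs)),
      x = xs, y = ys, pixel_spacing_mm = c(px, px),
      slice_index = si, slice_z = sl$z,
      endo_contour = sl$endo_ed, epi_contour = sl$epi_ed,
      es_endo_contour = sl$endo_es, es_epi_contour = sl$epi_es,
      truth_scar = matrix(scar, nrow = length(xs))),
      class = "lge_slice")
  })
}

#' True infarct volume of a set of generated LGE slices
#' @param lge_slices list of `lge_slice`.
#' @param slice_thickness_mm slice spacing used as slab thickness.
#' @return volume in cm^3 from the retained pixel scar truth.
#' @export
lge_infarct_volume <- function(lge_slices, slice_thickness_mm) {
  v <- vapply(lge_slices, function(s)
    sum(s$truth_scar) * prod(s$pixel_spacing_mm) * slice_thickness_mm, 0)
  sum(v) / 1000
}

#' Simulate one complete synthetic subject
#'
#' @param config [lv_config()].
#' @param subject_id subject index (1-based); the subject seed is
#'   `config$seed + subject_id`.
#' @return list with `geometry`, `scar_field`, `emm`, `truth`, `strain`,
#'   `lge`, `subject_id`, `subject_seed`.
#' @export
simulate_subject <- function(config, subject_id) {
  seed <- config$seed + subject_id
  g0 <- generate_lv_geometry(config, seed)
  field <- generate_scar_field(g0$endo_mesh_ed, config, seed)
  g <- if (config$scar_akinesis_factor > 0)
    generate_lv_geometry(config, seed, scar_field = field) else g0
  em <- sample_emm_map(g$endo_mesh_ed, field, config, seed,
                       subject_id = subject_id)
  st <- generate_strain_curves(g$slice_stack, field, config, seed,
                               subject_id = subject_id)
  lge <- generate_lge_slices(g$slice_stack, field, config, seed)
  list(subject_id = subject_id, subject_seed = seed, geometry = g,
       scar_field = field, emm = em$emm, truth = em$truth,
       strain = st, lge = lge)
}

#' Simulate a full synthetic cohort
#' @param config [lv_config()].
#' @return object of class `lv_study`: list of subjects plus the config.
#' @export
simulate_study <- function(config = lv_config()) {
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) simulate_subject(config, i))
  structure(list(subjects = subjects, config = config), class = "lv_study")
}

#' @export
print.lv_study <- function(x, ...) {
  np <- vapply(x$subjects, function(s) nrow(s$emm$points), 0L)
  cat(sprintf("lv_study: %d subjects, %d EMM points total (%.0f +/- %.0f per subject)\n",
              length(x$subjects), sum(np), mean(np), stats::sd(np)))
  invisible(x)
}

#' Simulate clustered binary data from a random-intercept logistic model
#'
#' Direct simulation oracle for the scar-model estimators: standard-normal
#' predictors, per-subject random intercepts and Bernoulli outcomes from
#' the logistic model.  Used for parameter-recovery and null experiments.
#'
#' @param beta named fixed-effect vector (log-odds per SD).
#' @param beta0 intercept (log-odds).
#' @param sigma_u random-intercept SD.
#' @param n_subjects,points_per_subject cluster structure.
#' @param seed RNG seed.
#' @return data.frame with predictor columns, `scar_label`, `subject_id`.
#' @export
simulate_glmm_table <- function(beta = c(uv = -2, bv = -1, lls = -0.3, lat = -0.2),
                                beta0 = -1.2, sigma_u = 0.5,
                                n_subjects = 13, points_per_subject = 61,
                                seed = 1) {
  set.seed(seed)
  n <- n_subjects * points_per_subject
  subj <- rep(seq_len(n_subjects), each = points_per_subject)
  X <- matrix(stats::rnorm(n * length(beta)), ncol = length(beta),
              dimnames = list(NULL, names(beta)))
  u <- stats::rnorm(n_subjects, 0, sigma_u)
  lp <- beta0 + as.vector(X %*% beta) + u[subj]
  y <- stats::rbinom(n, 1, stats::plogis(lp))
  out <- as.data.frame(X)
  out$scar_label <- y
  out$subject_id <- subj
  out
}
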