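#' Configuration for the synthetic LV study generator
#'
#' Collects every tunable of the synthetic cohort in one validated object.
#' Defaults emulate the study conditions of a chronic porcine infarct
#' cohort: 13 subjects, about 112 EMM points each covering the endocardium
#' homogeneously, an apicoseptal mostly-transmural scar covering about 21%
#' of the LV endocardial surface, healthy/scar median circumferential peak
#' strain of -26.0% / -15.7%, a rigid EMM-to-MRI misalignment of at most 10
#' degrees, and an end-diastolic cavity volume near 110.7 ml.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param points_mean,points_sd,points_min per-subject EMM point count:
#'   normal draw (mean 112, SD 41) truncated below at `points_min`.
#' @param endo_long_axis_mm endocardial semi-long-axis (apex to equator).
#' @param endo_short_axis_mm length-2 endocardial short semi-axes (mm); a
#'   mildly elliptical cross-section, as LV short-axis sections are not
#'   perfect circles.
#' @param base_angle_deg polar angle (from the apex) at which the ventricle
#'   is truncated by the basal plane.
#' @param wall_thickness_ed_mm end-diastolic wall thickness.
#' @param wall_thickening_mm systolic increase in wall thickness.
#' @param es_long_axis_scale,es_short_axis_scale end-systolic contraction
#'   factors of the endocardial axes.
#' @param subject_scale_sd log-SD of the per-subject global size factor.
#' @param scar_center_theta_deg,scar_center_phi_deg angular position of the
#'   scar centre (polar angle from apex; azimuth from +x, counterclockwise;
#'   default apicoseptal/apicoanterior).
#' @param scar_center_jitter_deg per-subject SD of the scar centre angles.
#' @param scar_surface_fraction,scar_fraction_sd target endocardial surface
#'   fraction with transmurality >= 50% and its between-subject SD.
#' @param border_zone_width_mm width of the non-transmural border zone over
#'   which transmurality ramps from 100 to 0 (small: the emulated infarct
#'   model is mostly transmural).
#' @param scar_akinesis_factor fraction of systolic radial contraction lost
#'   in fully transmural scar (couples scar to wall thickening and strain).
#' @param emm_params data.frame with columns `param`, `healthy_mean`,
#'   `healthy_sd`, `scar_mean`, `scar_sd` for uv (mV), bv (mV), lls (%),
#'   lat (ms).  UV and BV are drawn from truncated normals (>= 0).
#' @param strain_healthy_median_pct,strain_scar_median_pct peak-strain
#'   medians for healthy and (non-akinetic) scar sectors.
#' @param strain_healthy_sd,strain_scar_sd corresponding SDs.
#' @param akinetic_scar_fraction fraction of scar sectors generated
#'   near-akinetic (peak shortening magnitude < 7.5%).
#' @param akinetic_threshold_pct peak-strain threshold of the akinetic
#'   filter (% strain; sectors with `strain_max > threshold` are akinetic).
#' @param n_frames,cycle_ms temporal sampling of strain curves.
#' @param onset_healthy_ms,onset_scar_delay_ms,peak_healthy_ms,
#'   onset_jitter_ms,peak_jitter_ms timing of the shortening ramp.
#' @param slice_thickness_mm short-axis slice spacing.
#' @param basal_gap_mm extent of the most basal LV not covered by the MRI
#'   slice stack; EMM points mapped there end up basal of the mesh and are
#'   excluded during registration, as in catheter practice.
#' @param lge_pixel_mm,lge_remote_intensity,lge_enhancement,lge_noise_sd
#'   LGE image formation: pixel spacing, remote myocardial intensity,
#'   hyperenhancement factor (>= 2x remote) and additive Gaussian noise SD.
#' @param misalignment_rot_deg_max,misalignment_trans_mm bounds of the true
#'   rigid misalignment between the EMM cloud and the MRI mesh.
#' @param noise_sd_mm isotropic positional noise SD of EMM points.
#' @param n_theta,n_phi mesh resolution (rings, points per ring).
#' @param n_sectors_tm,n_sectors_strain circumferential sector counts for
#'   transmurality/wall metrics (80) and strain (48).
#' @param seed master seed; per-subject seeds are `seed + subject index`.
#' @return validated object of class `lv_config`.
#' @export
lv_config <- function(n_subjects = 13,
                      points_mean = 112, points_sd = 41, points_min = 80,
                      endo_long_axis_mm = 45,
                      endo_short_axis_mm = c(29, 24),
                      base_angle_deg = 120,
                      wall_thickness_ed_mm = 8,
                      wall_thickening_mm = 3,
                      es_long_axis_scale = 0.95,
                      es_short_axis_scale = 0.75,
                      subject_scale_sd = 0.06,
                      scar_center_theta_deg = 35,
                      scar_center_phi_deg = 135,
                      scar_center_jitter_deg = 8,
                      scar_surface_fraction = 0.21,
                      scar_fraction_sd = 0.084,
                      border_zone_width_mm = 4,
                      scar_akinesis_factor = 0.25,
                      emm_params = default_emm_params(),
                      strain_healthy_median_pct = -26.0,
                      strain_scar_median_pct = -15.7,
                      strain_healthy_sd = 9,
                      strain_scar_sd = 5,
                      akinetic_scar_fraction = 0.6,
                      akinetic_threshold_pct = -7.5,
                      n_frames = 30, cycle_ms = 800,
                      onset_healthy_ms = 80, onset_scar_delay_ms = 40,
                      peak_healthy_ms = 350,
                      onset_jitter_ms = 12, peak_jitter_ms = 20,
                      slice_thickness_mm = 5,
                      basal_gap_mm = 6,
                      lge_pixel_mm = 1.0,
                      lge_remote_intensity = 1.0,
                      lge_enhancement = 2.5,
                      lge_noise_sd = 0.08,
                      misalignment_rot_deg_max = 10,
                      misalignment_trans_mm = 5,
                      noise_sd_mm = 2.0,
                      n_theta = 48, n_phi = 72,
                      n_sectors_tm = 80, n_sectors_strain = 48,
                      seed = 1) {
  cfg <- as.list(environment())
  lengths_pos <- c("endo_long_axis_mm", "wall_thickness_ed_mm",
                   "slice_thickness_mm", "lge_pixel_mm", "cycle_ms")
  for (nm in lengths_pos)
    if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] <= 0))
      stop(sprintf("configuration error: %s must be positive", nm))
  if (length(endo_short_axis_mm) != 2 || any(endo_short_axis_mm <= 0))
    stop("configuration error: endo_short_axis_mm must be two positive lengths")
  if (scar_surface_fraction < 0 || scar_surface_fraction >= 1)
    stop("configuration error: scar_surface_fraction must be in [0, 1)")
  if (misalignment_rot_deg_max > 10)
    stop("configuration error: misalignment_rot_deg_max must be <= 10 degrees")
  if (border_zone_width_mm <= 0)
    stop("configuration error: border_zone_width_mm must be positive")
  if (n_frames < 3)
    stop("configuration error: at least 3 strain time samples are required")
  ep <- emm_params
  need <- c("param", "healthy_mean", "healthy_sd", "scar_mean", "scar_sd")
  if (!all(need %in% names(ep)) || !setequal(ep$param, c("uv", "bv", "lls", "lat")))
    stop("configuration error: emm_params must define uv, bv, lls, lat")
  if (ep$scar_mean[ep$param == "uv"] >= ep$healthy_mean[ep$param == "uv"] ||
      ep$scar_mean[ep$param == "bv"] >= ep$healthy_mean[ep$param == "bv"])
    stop("configuration error: scar UV/BV means must be below healthy means")
  if (strain_scar_median_pct <= strain_healthy_median_pct)
    stop("configuration error: scar strain must be less negative than healthy")
  class(cfg) <- "lv_config"
  cfg
}

#' Default healthy/scar EMM parameter distributions
#'
#' Class-conditional normal distributions for the four catheter-derived
#' parameters.  Values are realistic NOGA-range defaults with unipolar
#' voltage as the strongest scar discriminator, followed by bipolar
#' voltage, then the mechanical parameters; the study they emulate reports
#' no per-tissue summary statistics, so these remain fully configurable.
#'
#' @return data.frame with one row per parameter.
#' @export
default_emm_params <- function() {
  data.frame(
    param        = c("uv", "bv", "lls", "lat"),
    healthy_mean = c(12.0, 3.5, 12.0, 0.0),
    healthy_sd   = c(3.0, 1.2, 6.0, 15.0),
    scar_mean    = c(6.5, 1.6, 6.0, -6.0),
    scar_sd      = c(2.5, 1.0, 6.0, 16.0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.lv_config <- function(x, ...) {
  cat(sprintf(paste0(
    "lv_config: %d subjects, %.0f +/- %.0f EMM points/subject (min %d)\n",
    "  endo axes %.1f x %.1f x %.1f mm, wall %.1f mm, scar fraction %.2f\n",
    "  misalignment <= %.1f deg / %.1f mm, seed %d\n"),
    x$n_subjects, x$points_mean, x$points_sd, x$points_min,
    x$endo_long_axis_mm, x$endo_short_axis_mm[1], x$endo_short_axis_mm[2],
    x$wall_thickness_ed_mm, x$scar_surface_fraction,
    x$misalignment_rot_deg_max, x$misalignment_trans_mm, as.integer(x$seed)))
  invisible(x)
}

#' Default end-to-end run configuration
#'
#' Bundles the generator configuration with the registration, projection
#' and model settings used by [run_pipeline()].  The defaults are the
#' analysis settings of the emulated study: 10 degree rotation constraint,
#' 5 mm distance exclusion and IDW radius, transmurality dichotomized at
#' 50%, 500 bootstrap replicates, 80/48 circumferential sectors and the
#' -7.5% akinetic threshold.
#'
#' @param lv [lv_config()] for the synthetic cohort.
#' @param seed master seed (overrides `lv$seed` when given).
#' @param n_boot bootstrap replicates for intervals and optimism correction.
#' @return object of class `run_config`.
#' @export
run_config <- function(lv = lv_config(), seed = lv$seed, n_boot = 500) {
  lv$seed <- seed
  structure(list(
    lv = lv,
    max_rotation_deg = 10,
    max_dist_mm = 5,
    idw_radius_mm = 5,
    idw_power = 1,
    tm_threshold_pct = 50,
    n_boot = n_boot,
    prob_threshold = 0.5,
    n_sectors_tm = 80,
    n_sectors_strain = 48,
    akinetic_threshold_pct = -7.5,
    seed = seed
  ), class = "run_config")
}

# deterministic per-operation seed derived from a subject seed; keeps every
# generator operation independently reproducible for a given (config, seed)
derive_seed <- function(subject_seed, offset) {
  as.integer((as.numeric(subject_seed) * 101 + offset) %% 2147483647)
}
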