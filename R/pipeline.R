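#' Run the full synthetic multimodality analysis pipeline
#'
#' End-to-end orchestration: simulate the synthetic cohort, quantify LGE
#' scar and wall metrics per slice, transfer sector values to the
#' end-diastolic endocardial mesh, extract strain features, register each
#' EMM cloud to its mesh (apex pre-alignment + rotation-constrained ICP),
#' apply distance/basal exclusions, project MRI values onto the retained
#' points, fit the random-intercept logistic scar model with AIC backward
#' selection, bootstrap the odds-ratio intervals, run the optimism-
#' corrected internal validation, and fit the univariable EMM-versus-MRI
#' linear associations.  All stages draw only from seeds derived from
#' `config$seed`, so a fixed seed reproduces the report bit-identically.
#'
#' @param config [run_config()].
#' @param outdir optional directory; when given, stage outputs are
#'   persisted as CSV/JSON (and PNG maps when `render = TRUE`).
#' @param nagq quadrature nodes for the logistic mixed model.
#' @param slope_method calibration-slope estimator (`"mixed"`/`"fixed"`).
#' @param render write per-subject scar/prediction maps.
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL, nagq = 1,
                         slope_method = "mixed", render = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(fmt, ...) message(sprintf(paste0("[emmscar] ", fmt), ...))

  stage("simulate: %d subjects, seed %d", config$lv$n_subjects, config$seed)
  study <- simulate_study(config$lv)

  registrations <- list()
  meshes <- list()
  features_all <- list()
  slice_info <- list()
  scar_frac <- inf_vol <- numeric(length(study$subjects))
  for (i in seq_along(study$subjects)) {
    sub <- study$subjects[[i]]
    sid <- as.character(sub$subject_id)
    sectors <- quantify_lge(sub$lge, n_sectors = config$n_sectors_tm)
    mesh <- build_endo_mesh(sub$geometry$slice_stack, phase = "ED")
    mesh <- sectors_to_mesh(sectors, mesh)
    meshes[[sid]] <- mesh
    reg <- register_emm(sub$emm, mesh,
                        max_rotation_deg = config$max_rotation_deg,
                        max_dist_mm = config$max_dist_mm)
    registrations[[sid]] <- reg
    feats <- strain_feature_table(sub$strain$curves,
                                  threshold_pct = config$akinetic_threshold_pct)
    features_all[[sid]] <- feats
    si <- unique(sectors[, c("slice_index", "slice_z", "cx", "cy")])
    si$subject_id <- sub$subject_id
    slice_info[[sid]] <- si
    va <- mesh_vertex_areas(sub$geometry$endo_mesh_ed)
    scar_frac[i] <- sum(va[sub$scar_field$tm >= 50]) / sum(va)
    inf_vol[i] <- lge_infarct_volume(sub$lge, config$lv$slice_thickness_mm)
    stage("subject %s: %d points, reg error %.2f +/- %.2f mm (%d retained)",
          sid, nrow(sub$emm$points), reg$stats$mean_mm, reg$stats$sd_mm,
          reg$stats$n)
  }
  features_all <- do.call(rbind, features_all)
  slice_info <- do.call(rbind, slice_info)

  stage("project: IDW radius %.1f mm, TM threshold %.0f%%",
        config$idw_radius_mm, config$tm_threshold_pct)
  md <- match_dataset(registrations, meshes,
                      radius_mm = config$idw_radius_mm,
                      power = config$idw_power,
                      tm_threshold_pct = config$tm_threshold_pct)
  matched <- md$matched
  if (length(unique(matched$scar_label)) < 2)
    stop("scar_model stage: single-class outcome after matching")

  all_dist <- unlist(lapply(registrations, function(r) r$retained$distance_mm))
  reg_error <- list(mean_mm = mean(all_dist), sd_mm = stats::sd(all_dist),
                    n = length(all_dist))

  stage("fit: logistic mixed model on %d points, backward AIC", nrow(matched))
  table <- scale_predictors(matched)
  sel <- backward_select_aic(table, nagq = nagq)
  orci <- bootstrap_or_ci(table, sel$predictors, n_boot = config$n_boot,
                          seed = config$seed + 1000, nagq = nagq)
  stage("validate: %d bootstrap replicates", config$n_boot)
  val <- internal_validation(table, sel$predictors, n_boot = config$n_boot,
                             seed = config$seed + 2000,
                             prob_threshold = config$prob_threshold,
                             nagq = nagq, slope_method = slope_method)

  stage("assoc: univariable EMM vs feature-tracking comparisons")
  paired <- pair_emm_strain(matched, features_all, slice_info,
                            n_sectors = config$n_sectors_strain)
  assoc <- assoc_emm_ft(paired)

  truth_all <- do.call(rbind, lapply(study$subjects, function(s) s$strain$truth))
  fkey <- paste(features_all$subject_id, features_all$slice_index,
                features_all$sector_index)
  tkey <- paste(truth_all$subject_id, truth_all$slice_index,
                truth_all$sector_index)
  sector_scar <- truth_all$scar[match(fkey, tkey)]
  incl <- !features_all$akinetic
  strain_summary <- list(
    healthy_median_pct = stats::median(
      features_all$strain_max_pct[incl & !sector_scar], na.rm = TRUE),
    scar_median_pct = stats::median(
      features_all$strain_max_pct[incl & sector_scar], na.rm = TRUE),
    akinetic_lv_pct = 100 * mean(features_all$akinetic))

  report <- structure(list(
    seed = config$seed,
    n_subjects = config$lv$n_subjects,
    accounting = md$accounting,
    registration_error = reg_error,
    scar_surface_fraction = list(mean = mean(scar_frac), sd = stats::sd(scar_frac)),
    infarct_volume_cm3 = list(mean = mean(inf_vol), sd = stats::sd(inf_vol)),
    strain = strain_summary,
    selected_predictors = sel$predictors,
    or_table = orci$or_ci,
    validation = val,
    assoc = assoc,
    matched = matched), class = "run_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(matched, file.path(outdir, "matched_points.csv"),
                     row.names = FALSE)
    utils::write.csv(orci$or_ci, file.path(outdir, "odds_ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(assoc, file.path(outdir, "associations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tfs <- lapply(registrations, function(r) transform_to_list(r$transform))
    jsonlite::write_json(tfs, file.path(outdir, "transforms.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (render) {
      for (sid in names(meshes)) {
        pred <- predict_probability(val$fit,
                                    matched[matched$subject_id == sid, ])
        render_maps(meshes[[sid]],
                    cbind(matched[matched$subject_id == sid, ], prob = pred),
                    prefix = file.path(outdir, paste0("subject_", sid)))
      }
    }
  }
  report
}

#' Flatten a run report into JSON-ready lists
#' @param report `run_report`.
#' @export
report_to_list <- function(report) {
  val <- report$validation
  list(
    seed = report$seed,
    n_subjects = report$n_subjects,
    accounting = c(report$accounting$total,
                   list(per_subject = report$accounting$per_subject)),
    registration_error = report$registration_error,
    scar_surface_fraction = report$scar_surface_fraction,
    infarct_volume_cm3 = report$infarct_volume_cm3,
    strain = report$strain,
    selected_predictors = as.list(report$selected_predictors),
    odds_ratios = report$or_table,
    validation = list(
      c_statistic = val$c_statistic, c_ci = val$c_ci,
      within_subject_c = val$within_subject_c$weighted_c,
      calibration_slope = val$calibration_slope, slope_ci = val$slope_ci,
      optimism_corrected_c = val$optimism_corrected_c,
      optimism_corrected_slope = val$optimism_corrected_slope,
      sensitivity_pct = val$sensitivity_pct,
      specificity_pct = val$specificity_pct,
      n_boot = val$n_boot, n_boot_used = val$n_boot_used),
    associations = report$assoc)
}

#' @export
print.run_report <- function(x, ...) {
  a <- x$accounting$total
  cat(sprintf("run_report (seed %d, %d subjects)\n", x$seed, x$n_subjects))
  cat(sprintf("  points: %d registered, %d excluded (%.1f%%), %d matched\n",
              a$registered, a$excluded, a$excluded_pct, a$matched))
  cat(sprintf("  registration error %.2f +/- %.2f mm\n",
              x$registration_error$mean_mm, x$registration_error$sd_mm))
  cat(sprintf("  scar model predictors: %s\n",
              paste(x$selected_predictors, collapse = ", ")))
  print(x$validation)
  invisible(x)
}

#' Render scar-truth and prediction maps for one subject
#'
#' Writes two PNG figures: the MRI-derived transmurality field on the mesh
#' vertices and the model's predicted scar probability at the matched EMM
#' points, both as two-view (anterior x-z, lateral y-z) scatter
#' projections.  Colour ranges: transmurality 0-100%, probability 0-1.
#'
#' @param mesh annotated `surface_mesh` (field `tm_pct`).
#' @param predictions data.frame of matched points with a `prob` column.
#' @param prefix output path prefix; files `<prefix>_tm.png` and
#'   `<prefix>_pred.png`.
#' @return character vector of the written files (invisibly); a warning
#'   and no files when `predictions` is empty.
#' @export
render_maps <- function(mesh, predictions, prefix) {
  if (is.null(predictions) || nrow(predictions) == 0) {
    warning("no predictions to render")
    return(invisible(character()))
  }
  ramp <- grDevices::colorRamp(c("#2c7bb6", "#ffffbf", "#d7191c"))
  col_of <- function(v, lo, hi) {
    u <- pmin(1, pmax(0, (v - lo) / (hi - lo)))
    u[is.na(u)] <- 0
    grDevices::rgb(ramp(u), maxColorValue = 255)
  }
  two_view <- function(pts, cols, main) {
    graphics::par(mfrow = c(1, 2), mar = c(3, 3, 2, 1))
    graphics::plot(pts[, 1], pts[, 3], col = cols, pch = 16, cex = 0.6,
                   asp = 1, xlab = "x (mm)", ylab = "z (mm)", main = main)
    graphics::plot(pts[, 2], pts[, 3], col = cols, pch = 16, cex = 0.6,
                   asp = 1, xlab = "y (mm)", ylab = "z (mm)", main = main)
  }
  f_tm <- paste0(prefix, "_tm.png")
  grDevices::png(f_tm, width = 900, height = 450)
  tm <- mesh$fields$tm_pct
  two_view(mesh$vertices, col_of(tm, 0, 100), "LGE transmurality (%)")
  grDevices::dev.off()
  f_pred <- paste0(prefix, "_pred.png")
  grDevices::png(f_pred, width = 900, height = 450)
  two_view(emm_positions(predictions), col_of(predictions$prob, 0, 1),
           "predicted scar probability")
  grDevices::dev.off()
  invisible(c(f_tm, f_pred))
}
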