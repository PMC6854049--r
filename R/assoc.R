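#' Univariable linear mixed-effects association
#'
#' Fits `y = a + g*x + u_j + e` with a random intercept per subject by
#' maximum likelihood (ML, not REML, so variance components of nested
#' models are comparable for the explained-variance measure), together
#' with the intercept-only null model on the same rows.  The p-value is a
#' Wald z-test on the fixed slope.
#'
#' @param x predictor values.
#' @param y outcome values.
#' @param subjects cluster ids.
#' @param predictor,outcome labels stored in the result.
#' @return object of class `assoc_result`: `slope`, `se`, `p_value`,
#'   variance components of full and null models and `r2_sb`.
#' @export
fit_lmm_univariable <- function(x, y, subjects, predictor = "x", outcome = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; subjects <- subjects[ok]
  if (length(unique(subjects)) < 2) stop("at least 2 subjects required")
  if (stats::sd(x) < 1e-12) stop("zero-variance predictor")
  dat <- data.frame(x = x, y = y, subject = factor(subjects))
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | subject), data = dat, REML = FALSE)))
  null <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | subject), data = dat, REML = FALSE)))
  slope <- unname(lme4::fixef(full)[["x"]])
  se <- tryCatch(
    suppressWarnings(sqrt(diag(as.matrix(stats::vcov(full))))[["x"]]),
    error = function(e) NA_real_)  # degenerate (noiseless) fits
  vc <- function(m) c(sigma_u2 = unname(lme4::VarCorr(m)$subject[1]),
                      sigma_e2 = stats::sigma(m)^2)
  vf <- vc(full)
  vn <- vc(null)
  res <- structure(list(
    predictor = predictor, outcome = outcome, n = length(y),
    slope = slope, se = se,
    p_value = if (is.finite(se)) 2 * stats::pnorm(-abs(slope / se)) else NA_real_,
    sigma_e2_full = vf[["sigma_e2"]], sigma_u2_full = vf[["sigma_u2"]],
    sigma_e2_null = vn[["sigma_e2"]], sigma_u2_null = vn[["sigma_u2"]],
    r2_sb = NA_real_), class = "assoc_result")
  res$r2_sb <- snijders_bosker_r2(res, res_null = res)
  res
}

#' Snijders-Bosker explained variance of a mixed model
#'
#' Proportional reduction in total (residual + intercept) variance of the
#' full model relative to the null model:
#' `R2 = 1 - (se2_full + su2_full) / (se2_null + su2_null)`.  Small
#' negative values can arise from the ML approximation and are flagged.
#'
#' Accepts either two `assoc_result` objects (full vs null) or raw
#' variance components via `full = c(sigma_e2, sigma_u2)` and
#' `res_null = c(sigma_e2, sigma_u2)`.
#'
#' @param full `assoc_result` or length-2 numeric `(sigma_e2, sigma_u2)`.
#' @param res_null the null model, same forms.
#' @return explained-variance fraction.
#' @export
snijders_bosker_r2 <- function(full, res_null) {
  comp <- function(obj, which) {
    if (inherits(obj, "assoc_result"))
      c(obj[[paste0("sigma_e2_", which)]], obj[[paste0("sigma_u2_", which)]])
    else as.numeric(obj)
  }
  f <- comp(full, "full")
  n <- comp(res_null, "null")
  tot_null <- sum(n)
  if (tot_null <= 0) stop("null model total variance is zero")
  r2 <- 1 - sum(f) / tot_null
  if (r2 < -1e-6) attr(r2, "flag") <- "negative R2 (ML approximation)"
  r2
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope %.4f (SE %.4f), p = %.3g, R2_SB = %.4f (n = %d)\n",
              x$outcome, x$predictor, x$slope, x$se, x$p_value, x$r2_sb, x$n))
  invisible(x)
}

#' Pair EMM points with strain sectors
#'
#' Assigns each matched EMM point the strain sector whose wedge contains
#' it on the nearest slice (nearest slice by long-axis coordinate, wedge
#' by azimuth about the slice's cavity centroid, on the 48-sector grid).
#'
#' @param matched matched-point data.frame with registered positions.
#' @param strain_features per-sector feature table from
#'   [strain_feature_table()].
#' @param slice_info data.frame with `subject_id`, `slice_index`,
#'   `slice_z`, `cx`, `cy` (one row per slice).
#' @param n_sectors strain sector count (default 48).
#' @return `matched` with strain feature columns appended.
#' @export
pair_emm_strain <- function(matched, strain_features, slice_info,
                            n_sectors = 48) {
  out <- matched
  out$strain_max_pct <- out$ttp_max_ms <- out$t_onset_ms <- NA_real_
  out$akinetic <- NA
  for (s in unique(matched$subject_id)) {
    mrows <- which(matched$subject_id == s)
    sl <- slice_info[slice_info$subject_id == s, ]
    ft <- strain_features[strain_features$subject_id == s, ]
    if (!nrow(sl) || !nrow(ft)) next
    si <- vapply(matched$z_mm[mrows],
                 function(z) sl$slice_index[which.min(abs(sl$slice_z - z))], 0L)
    for (k in seq_along(mrows)) {
      row <- sl[sl$slice_index == si[k], ][1, ]
      ang <- atan2(matched$y_mm[mrows[k]] - row$cy,
                   matched$x_mm[mrows[k]] - row$cx)
      sec <- sector_of_angle(ang, n_sectors) - 1L
      hit <- ft[ft$slice_index == si[k] & ft$sector_index == sec, ]
      if (nrow(hit)) {
        out$strain_max_pct[mrows[k]] <- hit$strain_max_pct[1]
        out$ttp_max_ms[mrows[k]] <- hit$ttp_max_ms[1]
        out$t_onset_ms[mrows[k]] <- hit$t_onset_ms[1]
        out$akinetic[mrows[k]] <- hit$akinetic[1]
      }
    }
  }
  out
}

#' Univariable EMM-versus-MRI association table
#'
#' One-to-one linear mixed-model comparisons of the catheter mechanical
#' parameters with the MRI mechanical parameters: LLS against WT, WT% and
#' peak strain; LAT against onset and time-to-peak.  Akinetic sectors
#' enter with their observed (sub-threshold) peak strain; their timing
#' features are undefined and those rows drop from the timing models.
#'
#' @param paired data.frame from [pair_emm_strain()] (matched points with
#'   projected WT/WT% and paired strain features).
#' @return data.frame with slope, SE, p-value and Snijders-Bosker R2 per
#'   comparison.
#' @export
assoc_emm_ft <- function(paired) {
  pairs <- list(
    c("wt_mm", "lls_pct"),
    c("wt_frac_pct", "lls_pct"),
    c("strain_max_pct", "lls_pct"),
    c("t_onset_ms", "lat_ms"),
    c("ttp_max_ms", "lat_ms"))
  rows <- lapply(pairs, function(pr) {
    res <- tryCatch(
      fit_lmm_univariable(paired[[pr[1]]], paired[[pr[2]]],
                          paired$subject_id,
                          predictor = pr[1], outcome = pr[2]),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(predictor = res$predictor, outcome = res$outcome, n = res$n,
               slope = res$slope, se = res$se, p_value = res$p_value,
               r2_sb = as.numeric(res$r2_sb))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
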