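#' Peak strain and time-to-peak of a strain curve
#'
#' `strain_max` is the most negative strain value of the curve (peak
#' shortening) and `ttp_max` the time of its first attainment (ties go to
#' the earliest time).
#'
#' @param time_ms strictly increasing sample times (ms).
#' @param strain_pct strain samples (%, negative = shortening).
#' @return list with `strain_max_pct` and `ttp_max_ms` (both `NA` when all
#'   samples are missing).
#' @export
peak_features <- function(time_ms, strain_pct) {
  ok <- is.finite(strain_pct)
  if (!any(ok)) return(list(strain_max_pct = NA_real_, ttp_max_ms = NA_real_))
  if (length(time_ms) < 3) stop("a strain curve needs at least 3 samples")
  if (any(diff(time_ms) <= 0)) stop("time samples must be strictly increasing")
  i <- which(strain_pct == min(strain_pct[ok]))[1]
  list(strain_max_pct = strain_pct[i], ttp_max_ms = time_ms[i])
}

#' Onset time of shortening (tangent method)
#'
#' Locates the steepest negative slope before the shortening peak, fits
#' the tangent line through that segment's midpoint, and returns its
#' intersection with the pre-shortening baseline (the mean strain over the
#' samples before the steepest segment, or 0 when none exist), clamped to
#' `[t[1], ttp_max]`.  Returns `NA` when the curve has no negative slope
#' anywhere before the peak (e.g. a flat akinetic trace).
#'
#' @param time_ms,strain_pct the sampled curve.
#' @return onset time in ms, or `NA`.
#' @export
onset_time <- function(time_ms, strain_pct) {
  pk <- peak_features(time_ms, strain_pct)
  if (!is.finite(pk$strain_max_pct) || pk$strain_max_pct >= 0) return(NA_real_)
  ip <- match(pk$ttp_max_ms, time_ms)
  if (ip < 2) return(NA_real_)
  slopes <- diff(strain_pct[1:ip]) / diff(time_ms[1:ip])
  if (all(!is.finite(slopes)) || min(slopes, na.rm = TRUE) >= 0) return(NA_real_)
  smin <- min(slopes, na.rm = TRUE)
  # earliest segment attaining the steepest slope, with a relative tolerance
  # so exact ties on a sampled linear ramp are not broken by rounding noise
  k <- which(slopes <= smin + 1e-8 * abs(smin))[1]
  baseline <- if (k > 1) mean(strain_pct[1:k]) else 0
  t_mid <- (time_ms[k] + time_ms[k + 1]) / 2
  s_mid <- (strain_pct[k] + strain_pct[k + 1]) / 2
  t_on <- t_mid + (baseline - s_mid) / slopes[k]
  min(max(t_on, time_ms[1]), pk$ttp_max_ms)
}

#' Strain features for a set of curves
#'
#' Applies [peak_features()] and [onset_time()] to every (subject, slice,
#' sector) curve of a long-format strain table and attaches the akinetic
#' flag from [akinetic_filter()].  Curves with more than 20% missing
#' frames are flagged invalid rather than interpolated.
#'
#' @param curves long data.frame with `subject_id`, `slice_index`,
#'   `sector_index`, `time_ms`, `strain_pct`.
#' @param threshold_pct akinetic peak-strain threshold (default -7.5).
#' @return data.frame with one row per sector: `strain_max_pct`,
#'   `ttp_max_ms`, `t_onset_ms`, `akinetic`, `valid`.
#' @export
strain_feature_table <- function(curves, threshold_pct = -7.5) {
  key <- interaction(curves$subject_id, curves$slice_index,
                     curves$sector_index, drop = TRUE)
  rows <- lapply(split(curves, key), function(cu) {
    cu <- cu[order(cu$time_ms), ]
    miss <- mean(!is.finite(cu$strain_pct))
    valid <- miss <= 0.2
    pk <- if (valid) peak_features(cu$time_ms, cu$strain_pct)
          else list(strain_max_pct = NA_real_, ttp_max_ms = NA_real_)
    data.frame(subject_id = cu$subject_id[1], slice_index = cu$slice_index[1],
               sector_index = cu$sector_index[1],
               strain_max_pct = pk$strain_max_pct, ttp_max_ms = pk$ttp_max_ms,
               t_onset_ms = if (valid) onset_time(cu$time_ms, cu$strain_pct)
                            else NA_real_,
               valid = valid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$subject_id, out$slice_index, out$sector_index), ]
  out$akinetic <- akinetic_flag(out$strain_max_pct, threshold_pct)
  # akinetic sectors carry no timing features but stay in the table,
  # labelled, for the univariable linear association analysis
  out$ttp_max_ms[out$akinetic] <- NA_real_
  out$t_onset_ms[out$akinetic] <- NA_real_
  rownames(out) <- NULL
  out
}

akinetic_flag <- function(strain_max_pct, threshold_pct = -7.5) {
  !is.na(strain_max_pct) & strain_max_pct > threshold_pct
}

#' Akinetic-sector filter
#'
#' A sector is akinetic when its peak shortening magnitude is below the
#' threshold (i.e. `strain_max_pct > -7.5`): near-zero deformation usually
#' reflects poor feature tracking in infarcted wall.  Akinetic sectors are
#' excluded from the strain-feature analysis but retained, labelled, for
#' the linear association analysis.  The filter is idempotent.
#'
#' @param features data.frame from [strain_feature_table()].
#' @param threshold_pct peak-strain threshold (default -7.5).
#' @return list with `included` and `akinetic` data.frames.
#' @export
akinetic_filter <- function(features, threshold_pct = -7.5) {
  ak <- akinetic_flag(features$strain_max_pct, threshold_pct)
  features$akinetic <- ak
  list(included = features[!ak, , drop = FALSE],
       akinetic = features[ak, , drop = FALSE])
}
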