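#' Inverse-distance-weighted projection of a vertex field onto a point
#'
#' Averages the values of all mesh vertices within `radius_mm` of the
#' query point with weights `1 / d^power` (default power 1).  A vertex
#' coinciding with the query point (d < 1e-9 mm) returns its value
#' exactly.  Vertices with missing field values (outside slice coverage)
#' never contribute.  When no vertex with a defined value lies within the
#' radius the point is unmatchable and `NA` is returned.
#'
#' @param point length-3 position (mm).
#' @param mesh `surface_mesh` with the named field.
#' @param field_name per-vertex field to project.
#' @param radius_mm search radius (default 5).
#' @param power IDW exponent (default 1).
#' @return projected scalar, or `NA` if unmatchable.
#' @export
idw_project <- function(point, mesh, field_name, radius_mm = 5, power = 1) {
  f <- mesh$fields[[field_name]]
  if (is.null(f)) stop(sprintf("field '%s' not defined on mesh", field_name))
  ok <- !is.na(f)
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, as.numeric(point))^2))
  sel <- ok & d <= radius_mm
  if (!any(sel)) return(NA_real_)
  dd <- d[sel]
  vv <- f[sel]
  if (any(dd < 1e-9)) return(vv[which(dd < 1e-9)[1]])
  w <- 1 / dd^power
  sum(w * vv) / sum(w)
}

#' Dichotomize transmurality into the scar label
#'
#' Scar is transmurality at or above the threshold (>= 50% by default; the
#' boundary value 50 maps to scar).
#'
#' @param tm_pct transmurality % in \[0, 100\].
#' @param threshold_pct dichotomization threshold (default 50).
#' @return integer 0/1 labels.
#' @export
dichotomize_tm <- function(tm_pct, threshold_pct = 50) {
  if (any(!is.na(tm_pct) & (tm_pct < 0 | tm_pct > 100)))
    stop("transmurality must be within [0, 100]")
  as.integer(tm_pct >= threshold_pct)
}

#' Match retained EMM points to MRI-derived vertex fields
#'
#' Builds the model's row unit: one row per retained, matchable EMM point,
#' with projected transmurality, wall thickening and fractional thickening,
#' and the dichotomized scar label.  Also returns the point accounting per
#' subject: `matched = registered - excluded - unmatchable` always holds.
#'
#' @param registrations named list (one entry per subject) of
#'   [register_emm()] results.
#' @param meshes named list of annotated `surface_mesh` objects (fields
#'   `tm_pct`, `wt_mm`, `wt_frac_pct`), same names as `registrations`.
#' @param radius_mm,power IDW settings (defaults 5 mm, power 1).
#' @param tm_threshold_pct scar dichotomization threshold.
#' @return list with `matched` (data.frame) and `accounting` (per-subject
#'   and total counts).
#' @export
match_dataset <- function(registrations, meshes, radius_mm = 5, power = 1,
                          tm_threshold_pct = 50) {
  subjects <- names(registrations)
  if (is.null(subjects)) subjects <- as.character(seq_along(registrations))
  rows <- list()
  acct <- list()
  for (s in subjects) {
    reg <- registrations[[s]]
    mesh <- meshes[[s]]
    if (is.null(mesh)) stop(sprintf("subject %s has no mesh", s))
    ret <- reg$retained
    n_reg <- nrow(reg$retained) + nrow(reg$excluded)
    proj <- vapply(c("tm_pct", "wt_mm", "wt_frac_pct"), function(fn) {
      vapply(seq_len(nrow(ret)), function(i)
        idw_project(as.numeric(ret[i, c("x_mm", "y_mm", "z_mm")]), mesh, fn,
                    radius_mm = radius_mm, power = power), 0)
    }, numeric(nrow(ret)))
    proj <- matrix(proj, nrow = nrow(ret),
                   dimnames = list(NULL, c("tm_pct", "wt_mm", "wt_frac_pct")))
    # weighted averaging can overshoot the [0, 100] bounds by rounding eps
    proj[, "tm_pct"] <- pmin(100, pmax(0, proj[, "tm_pct"]))
    matchable <- !is.na(proj[, "tm_pct"])
    df <- cbind(ret[matchable, setdiff(names(ret), "exclusion_reason"),
                    drop = FALSE],
                as.data.frame(proj[matchable, , drop = FALSE]))
    df$scar_label <- dichotomize_tm(df$tm_pct, tm_threshold_pct)
    rows[[s]] <- df
    acct[[s]] <- data.frame(
      subject_id = s, registered = n_reg,
      excluded_distance = sum(reg$excluded$exclusion_reason == "distance"),
      excluded_basal = sum(reg$excluded$exclusion_reason == "basal"),
      unmatchable = sum(!matchable), matched = sum(matchable))
  }
  acct <- do.call(rbind, acct)
  rownames(acct) <- NULL
  total <- accounting_summary(sum(acct$registered),
                              sum(acct$excluded_distance) + sum(acct$excluded_basal),
                              n_subjects = length(subjects),
                              unmatchable = sum(acct$unmatchable))
  matched <- do.call(rbind, rows)
  rownames(matched) <- NULL
  list(matched = matched, accounting = list(per_subject = acct, total = total))
}

#' Point accounting summary
#'
#' The bookkeeping identities of the matching stage, usable directly on
#' printed counts: percentage excluded, matched points
#' (`registered - excluded - unmatchable`) and mean points per subject.
#'
#' @param registered total registered EMM points.
#' @param excluded points excluded by distance or basal position.
#' @param n_subjects number of subjects.
#' @param unmatchable retained points without vertices in IDW range.
#' @return list with `registered`, `excluded`, `excluded_pct`,
#'   `unmatchable`, `matched`, `mean_points_per_subject`.
#' @export
accounting_summary <- function(registered, excluded, n_subjects,
                               unmatchable = 0) {
  matched <- registered - excluded - unmatchable
  list(registered = registered, excluded = excluded,
       excluded_pct = 100 * excluded / registered,
       unmatchable = unmatchable, matched = matched,
       mean_points_per_subject = registered / n_subjects)
}
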