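#' Pixel-center coordinates of an LGE slice
#' @param slice `lge_slice`.
#' @return list with vectors `x`, `y` (length nx*ny, column-major like the
#'   intensity matrix).
#' @keywords internal
slice_grid <- function(slice) {
  list(x = rep(slice$x, times = length(slice$y)),
       y = rep(slice$y, each = length(slice$x)))
}

#' Myocardial pixel mask of an LGE slice
#'
#' Pixels whose centers lie inside the epicardial contour and outside the
#' endocardial contour (end-diastolic phase).
#'
#' @param slice `lge_slice`.
#' @return logical matrix matching the intensity grid.
#' @export
myocardium_mask <- function(slice) {
  g <- slice_grid(slice)
  m <- points_in_polygon(g$x, g$y, slice$epi_contour) &
    !points_in_polygon(g$x, g$y, slice$endo_contour)
  matrix(m, nrow = length(slice$x))
}

#' Full-width-at-half-maximum scar segmentation
#'
#' Scar pixels are the myocardial pixels with intensity at or above half of
#' the maximum myocardial intensity of the slice.  In a constant-intensity
#' myocardium every pixel clears its own half-maximum, so the whole wall is
#' flagged; this degenerate limit is intentional, documented behaviour of
#' the half-maximum rule.
#'
#' @param slice `lge_slice`.
#' @param myo optional precomputed myocardial mask.
#' @param override optional function `(mask, slice) -> mask` applied after
#'   thresholding; programmatic replacement for manual mask correction.
#' @return logical scar mask (attribute `threshold` carries the cutoff).
#' @export
fwhm_scar_mask <- function(slice, myo = NULL, override = NULL) {
  if (is.null(myo)) myo <- myocardium_mask(slice)
  if (!any(myo)) stop("geometry error: empty myocardium")
  thr <- 0.5 * max(slice$intensity[myo])
  mask <- myo & slice$intensity >= thr
  if (!is.null(override)) mask <- override(mask, slice) & myo
  attr(mask, "threshold") <- thr
  mask
}

# sector index (1-based) of pixel angles for n half-open wedges
# [theta_i, theta_{i+1}) counterclockwise from the +x image axis
sector_of_angle <- function(angle, n_sectors) {
  a <- angle %% (2 * pi)
  pmin(n_sectors, floor(a / (2 * pi / n_sectors)) + 1L)
}

#' Area-based infarct transmurality in circumferential sectors
#'
#' Partitions the myocardium into `n_sectors` angular wedges about the LV
#' cavity centroid (area centroid of the endocardial contour) and computes
#' per-wedge transmurality as 100 x scar pixel area / myocardial pixel
#' area.  Wedges without myocardial pixels are flagged missing (`NA`).
#'
#' @param slice `lge_slice`.
#' @param scar_mask logical mask from [fwhm_scar_mask()].
#' @param n_sectors number of wedges (default 80).
#' @return data.frame with `slice_index`, `slice_z`, `sector_index`
#'   (0-based), `tm_pct`, `n_myo_px`, sector mid-wall centroid coordinates
#'   and the cavity centroid (`cx`, `cy`).
#' @export
sector_transmurality <- function(slice, scar_mask, n_sectors = 80) {
  myo <- myocardium_mask(slice)
  if (any(scar_mask & !myo)) stop("scar mask must lie within the myocardium")
  g <- slice_grid(slice)
  ctr <- polygon_centroid(slice$endo_contour)
  sec <- sector_of_angle(atan2(g$y - ctr[2], g$x - ctr[1]), n_sectors)
  myo_v <- as.vector(myo)
  scar_v <- as.vector(scar_mask)
  n_myo <- tabulate(sec[myo_v], nbins = n_sectors)
  n_scar <- tabulate(sec[myo_v & scar_v], nbins = n_sectors)
  tm <- ifelse(n_myo > 0, 100 * n_scar / n_myo, NA_real_)
  cx_s <- ifelse(n_myo > 0,
                 tabulate_sum(sec[myo_v], g$x[myo_v], n_sectors) / n_myo, NA_real_)
  cy_s <- ifelse(n_myo > 0,
                 tabulate_sum(sec[myo_v], g$y[myo_v], n_sectors) / n_myo, NA_real_)
  data.frame(slice_index = slice$slice_index, slice_z = slice$slice_z,
             sector_index = seq_len(n_sectors) - 1L,
             tm_pct = tm, n_myo_px = n_myo,
             centroid_x_mm = cx_s, centroid_y_mm = cy_s,
             centroid_z_mm = slice$slice_z, cx = ctr[1], cy = ctr[2])
}

# sum of w by integer group (1..nbins)
tabulate_sum <- function(group, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Sector wall thickness and wall thickening
#'
#' Wall thickness is the mean radial endocardium-to-epicardium distance in
#' each wedge, measured along rays from the per-phase cavity centroid.
#' Wall thickening is `thickness_ES - thickness_ED` (mm) and fractional
#' thickening is its percentage of the end-diastolic thickness; sectors
#' with zero ED thickness are flagged missing.
#'
#' @param slice `lge_slice` carrying ED and ES contours.
#' @param n_sectors number of wedges (default 80).
#' @param rays_per_sector radial samples averaged per wedge.
#' @return data.frame with `sector_index` (0-based), `thickness_ed_mm`,
#'   `thickness_es_mm`, `wt_mm`, `wt_frac_pct`.
#' @export
wall_metrics <- function(slice, n_sectors = 80, rays_per_sector = 5) {
  if (is.null(slice$es_endo_contour) || is.null(slice$es_epi_contour))
    stop("ES contours are required for wall thickening")
  width <- 2 * pi / n_sectors
  ang <- as.vector(vapply(seq_len(n_sectors), function(k) {
    (k - 1) * width + width * (seq_len(rays_per_sector) - 0.5) / rays_per_sector
  }, numeric(rays_per_sector)))
  thick <- function(endo, epi) {
    ctr <- polygon_centroid(endo)
    polygon_radius(epi, ctr, ang) - polygon_radius(endo, ctr, ang)
  }
  sec <- rep(seq_len(n_sectors), each = rays_per_sector)
  th_ed <- tabulate_sum(sec, thick(slice$endo_contour, slice$epi_contour),
                        n_sectors) / rays_per_sector
  th_es <- tabulate_sum(sec, thick(slice$es_endo_contour, slice$es_epi_contour),
                        n_sectors) / rays_per_sector
  wt <- th_es - th_ed
  data.frame(slice_index = slice$slice_index, slice_z = slice$slice_z,
             sector_index = seq_len(n_sectors) - 1L,
             thickness_ed_mm = th_ed, thickness_es_mm = th_es,
             wt_mm = wt,
             wt_frac_pct = ifelse(th_ed > 0, 100 * wt / th_ed, NA_real_))
}

#' Quantify a full LGE slice set
#'
#' Runs FWHM segmentation, sector transmurality and wall metrics for every
#' slice and merges the per-sector tables.
#'
#' The half-maximum rule is only meaningful on slices that actually contain
#' hyperenhancement: on a lesion-free slice half of the maximum falls below
#' the remote myocardial intensity and the whole wall would be flagged.  A
#' reader makes that call visually; here an enhancement detector stands in
#' for it: a slice is segmented only when its maximum myocardial intensity
#' exceeds `enhancement_min` times the volume-wide median myocardial
#' intensity (a robust remote reference, since scar occupies a minority of
#' the wall volume); otherwise its scar mask is empty.
#'
#' @param lge_slices list of `lge_slice`.
#' @param n_sectors number of wedges per slice (default 80).
#' @param enhancement_min minimum max-to-remote intensity ratio for a slice
#'   to be considered enhanced (default 1.8; hyperenhancement is >= 2x).
#' @return data.frame of sector values across slices.
#' @export
quantify_lge <- function(lge_slices, n_sectors = 80, enhancement_min = 1.8) {
  myos <- lapply(lge_slices, myocardium_mask)
  remote_ref <- stats::median(unlist(Map(function(sl, m) sl$intensity[m],
                                         lge_slices, myos)))
  out <- Map(function(sl, myo) {
    enhanced <- max(sl$intensity[myo]) >= enhancement_min * remote_ref
    mask <- if (enhanced) fwhm_scar_mask(sl, myo = myo) else myo & FALSE
    tm <- sector_transmurality(sl, mask, n_sectors)
    wm <- wall_metrics(sl, n_sectors)
    cbind(tm, wm[, c("thickness_ed_mm", "thickness_es_mm", "wt_mm", "wt_frac_pct")])
  }, lge_slices, myos)
  do.call(rbind, out)
}

#' Transfer sector values onto mesh vertices
#'
#' Each mesh vertex receives the values of the sector whose wedge contains
#' it, on the slice nearest in long-axis coordinate.  Vertices more basal
#' than the most basal slice (beyond half a slice spacing) are flagged
#' unassigned (`NA`) and never contribute to later projections.
#'
#' @param sector_values data.frame from [quantify_lge()].
#' @param endo_mesh `surface_mesh` to annotate.
#' @param value_cols columns to transfer as per-vertex fields.
#' @return the mesh with `fields` extended.
#' @export
sectors_to_mesh <- function(sector_values, endo_mesh,
                            value_cols = c("tm_pct", "wt_mm", "wt_frac_pct")) {
  zs <- sort(unique(sector_values$slice_z))
  spacing <- if (length(zs) > 1) stats::median(diff(zs)) else Inf
  n_sectors <- max(sector_values$sector_index) + 1L
  v <- endo_mesh$vertices
  si <- vapply(v[, 3], function(z) which.min(abs(zs - z)), 0L)
  unassigned <- v[, 3] > max(zs) + spacing / 2
  out <- matrix(NA_real_, nrow(v), length(value_cols),
                dimnames = list(NULL, value_cols))
  for (k in seq_along(zs)) {
    rows <- sector_values[sector_values$slice_z == zs[k], ]
    rows <- rows[order(rows$sector_index), ]
    idx <- which(si == k & !unassigned)
    if (!length(idx)) next
    ang <- atan2(v[idx, 2] - rows$cy[1], v[idx, 1] - rows$cx[1])
    sec <- sector_of_angle(ang, n_sectors)
    out[idx, ] <- as.matrix(rows[sec, value_cols, drop = FALSE])
  }
  for (cn in value_cols) endo_mesh$fields[[cn]] <- out[, cn]
  endo_mesh
}
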