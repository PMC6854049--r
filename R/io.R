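#' Write an EMM map to CSV
#' @param emm `emm_map`.
#' @param path output CSV (subject_id, x_mm, y_mm, z_mm, uv_mv, bv_mv,
#'   lls_pct, lat_ms).
#' @export
write_emm_csv <- function(emm, path) {
  utils::write.csv(emm$points, path, row.names = FALSE)
  invisible(path)
}

#' Read an EMM map from CSV
#' @param path CSV written by [write_emm_csv()].
#' @return `emm_map`.
#' @export
read_emm_csv <- function(path) {
  pts <- utils::read.csv(path)
  need <- c("subject_id", "x_mm", "y_mm", "z_mm",
            "uv_mv", "bv_mv", "lls_pct", "lat_ms")
  if (!all(need %in% names(pts))) stop("missing EMM columns")
  structure(list(subject_id = pts$subject_id[1], points = pts),
            class = "emm_map")
}

#' Write strain curves to long-format CSV
#' @param curves data.frame from [generate_strain_curves()].
#' @param path output CSV.
#' @export
write_strain_csv <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' Read long-format strain curves
#' @param path CSV with subject_id, slice_index, sector_index, frame,
#'   time_ms, strain_pct.
#' @export
read_strain_csv <- function(path) utils::read.csv(path)

#' Write an LGE slice as a CSV intensity grid plus contour sidecars
#'
#' The intensity matrix goes to `<path>` and the four contours to
#' `<path base>_contours.csv`; pixel coordinates are stored in the header
#' row/column.
#'
#' @param slice `lge_slice`.
#' @param path output CSV for the intensity grid.
#' @export
write_lge_csv <- function(slice, path) {
  g <- slice$intensity
  dimnames(g) <- list(format(slice$x), format(slice$y))
  utils::write.csv(g, path)
  ct <- do.call(rbind, lapply(
    c("endo_contour", "epi_contour", "es_endo_contour", "es_epi_contour"),
    function(nm) data.frame(contour = nm, x = slice[[nm]][, 1],
                            y = slice[[nm]][, 2])))
  utils::write.csv(ct, sub("\\.csv$", "_contours.csv", path), row.names = FALSE)
  invisible(path)
}
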