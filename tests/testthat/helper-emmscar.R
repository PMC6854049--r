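# Shared fixtures, built in code.

# Constructed annular LGE slice: circular endo/epi contours, remote
# intensity 1, a scar of given angular extent and transmural depth at
# intensity `core`.  Pixel truth follows the construction exactly.
make_annulus_slice <- function(endo_r = 20, epi_r = 28, px = 0.5,
                               scar_arc = NULL, scar_depth_frac = 1,
                               remote = 1, core = 10,
                               es_endo_r = endo_r, es_epi_r = epi_r) {
  circ <- function(r, n = 180) {
    a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(r * cos(a), r * sin(a))
  }
  endo_poly <- circ(endo_r)
  epi_poly <- circ(epi_r)
  # half-pixel offset keeps pixel centers off the exact coordinate axes,
  # where the angular wedge assignment would be degenerate
  xs <- seq(-epi_r - 2 + px / 2, epi_r + 2, by = px)
  gx <- rep(xs, times = length(xs))
  gy <- rep(xs, each = length(xs))
  r <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  # same polygonal wall definition the quantifier uses, so pixel truth and
  # segmentation agree at the contour boundary
  myo <- points_in_polygon(gx, gy, epi_poly) &
    !points_in_polygon(gx, gy, endo_poly)
  scar <- rep(FALSE, length(r))
  if (!is.null(scar_arc)) {
    in_arc <- ang >= scar_arc[1] & ang < scar_arc[2]
    scar <- myo & in_arc & r <= endo_r + scar_depth_frac * (epi_r - endo_r)
  }
  inten <- ifelse(myo, ifelse(scar, core, remote), 0)
  structure(list(
    intensity = matrix(inten, nrow = length(xs)),
    x = xs, y = xs, pixel_spacing_mm = c(px, px),
    slice_index = 1L, slice_z = 0,
    endo_contour = circ(endo_r), epi_contour = circ(epi_r),
    es_endo_contour = circ(es_endo_r), es_epi_contour = circ(es_epi_r),
    truth_scar = matrix(scar, nrow = length(xs))), class = "lge_slice")
}

# brute-force pairwise concordance oracle (ties counted one half)
brute_force_auc <- function(labels, probabilities) {
  p1 <- probabilities[labels == 1]
  p0 <- probabilities[labels == 0]
  tot <- 0
  for (a in p1) for (b in p0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p1) * length(p0))
}

# small, fast generator configuration for structural tests
small_config <- function(...) {
  lv_config(n_subjects = 2, points_mean = 90, points_sd = 10,
            n_theta = 24, n_phi = 36, seed = 101, ...)
}

# tiny planar mesh whose first vertices sit at controlled distances from
# the origin; used for hand-computed IDW cases
idw_fixture_mesh <- function() {
  v <- rbind(c(1, 0, 0),    # distance 1 from origin
             c(0, 4, 0),    # distance 4
             c(10, 10, 0),  # out of the 5-mm radius
             c(11, 10, 0))
  f <- rbind(c(1, 2, 3), c(2, 3, 4))
  surface_mesh(v, f, fields = list(val = c(0, 100, 55, 70)))
}
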