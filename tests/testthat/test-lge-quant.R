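test_that("FWHM threshold is half the myocardial maximum", {
  sl <- make_annulus_slice(scar_arc = c(0, pi / 2), remote = 1, core = 10)
  mask <- fwhm_scar_mask(sl)
  expect_equal(attr(mask, "threshold"), 5)
  expect_identical(unname(as.vector(mask)), as.vector(sl$truth_scar))
  # constant-intensity myocardium: every pixel clears its own half-max
  flat <- make_annulus_slice(scar_arc = NULL, remote = 3)
  m_flat <- fwhm_scar_mask(flat)
  expect_identical(unname(as.vector(m_flat)), as.vector(myocardium_mask(flat)))
  # empty myocardium errors
  bad <- make_annulus_slice()
  bad$endo_contour <- bad$epi_contour
  expect_error(fwhm_scar_mask(bad), "empty myocardium")
})

test_that("adding intensity to the scar core never shrinks the mask", {
  sl <- make_annulus_slice(scar_arc = c(0, pi / 2), core = 4)
  m1 <- fwhm_scar_mask(sl)
  sl2 <- sl
  sl2$intensity[sl$truth_scar] <- sl$intensity[sl$truth_scar] + 2
  m2 <- fwhm_scar_mask(sl2)
  expect_true(all(m2[m1]))
})

test_that("sector transmurality recovers full-wall and half-wall arcs", {
  n <- 80
  sl <- make_annulus_slice(px = 0.5, scar_arc = c(0, pi / 2))
  tm <- sector_transmurality(sl, fwhm_scar_mask(sl), n)
  in_arc <- tm$sector_index < n / 4
  expect_true(all(abs(tm$tm_pct[in_arc] - 100) <= 2))
  expect_true(all(tm$tm_pct[!in_arc] == 0))
  # scar over exactly the inner half of the wall thickness; the area-based
  # value is 100 * (r_mid^2 - re^2) / (rp^2 - re^2), close to (but not
  # exactly) 50 because annular area grows with radius
  sl2 <- make_annulus_slice(endo_r = 25, epi_r = 31, px = 0.5,
                            scar_arc = c(0, pi / 2), scar_depth_frac = 0.5)
  tm2 <- sector_transmurality(sl2, fwhm_scar_mask(sl2), n)
  analytic <- 100 * (28^2 - 25^2) / (31^2 - 25^2)
  arc2 <- tm2$sector_index < n / 4
  expect_true(all(abs(tm2$tm_pct[arc2] - analytic) <= 2.5))
  expect_true(all(abs(tm2$tm_pct[arc2] - 50) <= 5))
  expect_true(all(tm2$tm_pct[!arc2] == 0))
  # empty mask -> all zero
  tm0 <- sector_transmurality(sl, myocardium_mask(sl) & FALSE, n)
  expect_true(all(tm0$tm_pct == 0))
  # bounds and exact partition of myocardial pixel counts
  expect_true(all(tm$tm_pct >= 0 & tm$tm_pct <= 100, na.rm = TRUE))
  expect_identical(sum(tm$n_myo_px), sum(myocardium_mask(sl)))
  expect_error(sector_transmurality(sl, !myocardium_mask(sl)),
               "within the myocardium")
})

test_that("rotating the slice by 90 degrees permutes sector values", {
  sl <- make_annulus_slice(px = 0.5, scar_arc = c(0, pi / 2))
  tm <- sector_transmurality(sl, fwhm_scar_mask(sl), 80)
  rot <- make_annulus_slice(px = 0.5, scar_arc = c(pi / 2, pi))
  tm_rot <- sector_transmurality(rot, fwhm_scar_mask(rot), 80)
  expect_equal(tm_rot$tm_pct[21:40], tm$tm_pct[1:20], tolerance = 1e-9)
})

test_that("wall metrics match analytic concentric circles", {
  # ED: endo 25, epi 33 (thickness 8); ES: endo 20, epi 33 (thickness 13)
  sl <- make_annulus_slice(endo_r = 25, epi_r = 33, px = 1,
                           es_endo_r = 20, es_epi_r = 33)
  wm <- wall_metrics(sl)
  expect_equal(wm$wt_mm, rep(5, 80), tolerance = 0.01)
  expect_equal(wm$wt_frac_pct, rep(62.5, 80), tolerance = 0.2)
  # identical phases -> zero thickening everywhere
  sl0 <- make_annulus_slice(endo_r = 25, epi_r = 33)
  wm0 <- wall_metrics(sl0)
  expect_equal(wm0$wt_mm, rep(0, 80), tolerance = 1e-9)
  expect_equal(wm0$wt_frac_pct, rep(0, 80), tolerance = 1e-9)
})

test_that("elliptical contours give smooth thickness and conserved area", {
  ell <- function(a, b, n = 240) {
    t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(a * cos(t), b * sin(t))
  }
  sl <- make_annulus_slice(endo_r = 20, epi_r = 30, px = 0.5)
  sl$endo_contour <- ell(20, 16)
  sl$epi_contour <- ell(30, 25)
  tm <- sector_transmurality(sl, myocardium_mask(sl) & FALSE, 80)
  # myocardial pixel areas across sectors sum to the annulus area
  pix_area <- sum(tm$n_myo_px) * 0.25
  ann_area <- abs(polygon_area(sl$epi_contour)) - abs(polygon_area(sl$endo_contour))
  expect_lt(abs(pix_area - ann_area) / ann_area, 0.01)
  wm <- wall_metrics(sl)
  expect_lt(max(abs(diff(wm$thickness_ed_mm))), 0.5)  # smooth variation
})

test_that("sector values transfer to mesh vertices by slice and wedge", {
  g <- generate_lv_geometry(small_config(), 1)
  # the generator mesh extends basally beyond the MRI slice coverage
  mesh <- g$endo_mesh_ed
  zs <- vapply(g$slice_stack$slices, function(s) s$z, 0)
  sv <- do.call(rbind, lapply(seq_along(zs), function(si)
    data.frame(slice_index = si, slice_z = zs[si], sector_index = 0:79,
               tm_pct = 7, wt_mm = 1.5, wt_frac_pct = 20, cx = 0, cy = 0)))
  m2 <- sectors_to_mesh(sv, mesh)
  covered <- mesh$vertices[, 3] <= max(zs)
  # uniform sector values propagate unchanged to all covered vertices
  expect_true(all(m2$fields$tm_pct[covered] == 7))
  # vertices more basal than the most basal slice stay unassigned
  basal <- mesh$vertices[, 3] > max(zs) + median(diff(sort(zs))) / 2
  expect_true(any(basal))
  expect_true(all(is.na(m2$fields$tm_pct[basal])))
  # single-slice direct lookup: value = sector index
  sv1 <- data.frame(slice_index = 1, slice_z = zs[1], sector_index = 0:79,
                    tm_pct = 0:79, wt_mm = 0, wt_frac_pct = 0, cx = 0, cy = 0)
  m3 <- sectors_to_mesh(sv1, mesh)
  v <- mesh$vertices[10, ]
  expected <- emmscar:::sector_of_angle(atan2(v[2], v[1]), 80) - 1
  expect_equal(m3$fields$tm_pct[10], expected)
})

test_that("quantified synthetic slices recover the true transmurality field", {
  cfg <- small_config()
  sub <- simulate_subject(cfg, 1)
  sectors <- quantify_lge(sub$lge)
  mesh <- sectors_to_mesh(sectors, build_endo_mesh(sub$geometry$slice_stack))
  tm_true <- tm_field_eval(sub$scar_field, mesh$vertices)
  ok <- !is.na(mesh$fields$tm_pct)
  agree <- mean((tm_true[ok] >= 50) == (mesh$fields$tm_pct[ok] >= 50))
  expect_gt(agree, 0.97)
  # zero-scar subject: quantification flags (almost) nothing
  cfg0 <- small_config(scar_surface_fraction = 0)
  sub0 <- simulate_subject(cfg0, 1)
  sec0 <- quantify_lge(sub0$lge)
  expect_true(all(sec0$tm_pct == 0, na.rm = TRUE))
})
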