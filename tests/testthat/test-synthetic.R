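test_that("invalid generator configurations are rejected", {
  expect_error(lv_config(wall_thickness_ed_mm = 0), "wall_thickness")
  expect_error(lv_config(endo_long_axis_mm = -3), "positive")
  expect_error(lv_config(scar_surface_fraction = 1), "scar_surface_fraction")
  expect_error(lv_config(misalignment_rot_deg_max = 12), "10")
  expect_error(lv_config(n_frames = 2), "3")
  expect_error(lv_config(lge_pixel_mm = 0), "positive")
})

test_that("same seed gives bit-identical geometry, EMM and images", {
  cfg <- small_config()
  a <- simulate_subject(cfg, 1)
  b <- simulate_subject(cfg, 1)
  expect_identical(a$geometry$endo_mesh_ed$vertices, b$geometry$endo_mesh_ed$vertices)
  expect_identical(a$emm$points, b$emm$points)
  expect_identical(a$strain$curves, b$strain$curves)
  expect_identical(a$lge[[2]]$intensity, b$lge[[2]]$intensity)
})

test_that("cohort cavity volume sits in the physiological band", {
  cfg <- lv_config(n_theta = 32, n_phi = 48)
  vols <- vapply(1:13, function(i)
    mesh_enclosed_volume(generate_lv_geometry(cfg, cfg$seed + i)$endo_mesh_ed) / 1000, 0)
  expect_gt(mean(vols), 90)
  expect_lt(mean(vols), 135)
  es <- mesh_enclosed_volume(generate_lv_geometry(cfg, 1)$endo_mesh_es)
  ed <- mesh_enclosed_volume(generate_lv_geometry(cfg, 1)$endo_mesh_ed)
  expect_lt(es, ed)  # systolic contraction
})

test_that("slicing the generated mesh reproduces the contour stack", {
  g <- generate_lv_geometry(lv_config(), 7)
  for (sl in g$slice_stack$slices[c(2, 5, 8)]) {
    pts <- mesh_slice_points(g$endo_mesh_ed, sl$z)
    r_mesh <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    ang <- atan2(pts[, 2], pts[, 1])
    r_contour <- polygon_radius(sl$endo_ed, c(0, 0), ang)
    expect_lt(max(abs(r_mesh - r_contour)), 0.1)
  }
})

test_that("scar field hits its calibrated surface fraction and core value", {
  cfg <- lv_config()
  g <- generate_lv_geometry(cfg, 4)
  f <- generate_scar_field(g$endo_mesh_ed, cfg, 4)
  va <- mesh_vertex_areas(g$endo_mesh_ed)
  realized <- sum(va[f$tm >= 50]) / sum(va)
  expect_lt(abs(realized - f$fraction_target) / f$fraction_target, 0.2)
  expect_true(all(f$tm >= 0 & f$tm <= 100))
  # vertex inside the core is fully transmural
  d <- sqrt(rowSums(sweep(g$endo_mesh_ed$vertices, 2, f$center)^2))
  expect_true(all(f$tm[d <= f$r_core] == 100))
  # zero fraction -> all-zero field
  f0 <- generate_scar_field(g$endo_mesh_ed, lv_config(scar_surface_fraction = 0), 4)
  expect_true(all(f0$tm == 0))
})

test_that("EMM sampling respects the surface, the truth transform and class means", {
  cfg0 <- small_config(misalignment_rot_deg_max = 0, misalignment_trans_mm = 0,
                       noise_sd_mm = 0)
  g <- generate_lv_geometry(cfg0, 2)
  f <- generate_scar_field(g$endo_mesh_ed, cfg0, 2)
  em <- sample_emm_map(g$endo_mesh_ed, f, cfg0, 2)
  # identity transform, zero noise -> every point on the mesh surface
  d <- closest_point_mesh(emm_positions(em$emm), g$endo_mesh_ed)$distance
  expect_lt(max(d), 1e-9)

  # with zero noise, the inverse of the truth transform returns the
  # perturbed cloud exactly to the surface
  cfg_rt <- small_config(noise_sd_mm = 0)
  em2 <- sample_emm_map(g$endo_mesh_ed, f, cfg_rt, 2)
  back <- apply_transform(invert_transform(em2$truth$true_transform),
                          emm_positions(em2$emm))
  expect_lt(max(abs(back - em2$truth$clean_points)), 1e-6)
  expect_lt(max(closest_point_mesh(back, g$endo_mesh_ed)$distance), 1e-6)
  expect_error(sample_emm_map(surface_mesh(matrix(0, 1, 3),
                                           matrix(integer(0), 0, 3)),
                              f, cfg, 2), "empty mesh")
})

test_that("scar-conditioned EMM distributions separate at large n (Welch)", {
  cfg <- lv_config(points_mean = 10000, points_sd = 0, points_min = 10000,
                   n_theta = 24, n_phi = 36)
  g <- generate_lv_geometry(cfg, 3)
  f <- generate_scar_field(g$endo_mesh_ed, cfg, 3)
  em <- sample_emm_map(g$endo_mesh_ed, f, cfg, 3)
  sc <- em$truth$scar_label == 1
  wt <- stats::t.test(em$emm$points$uv_mv[sc], em$emm$points$uv_mv[!sc],
                      alternative = "less")
  expect_lt(wt$p.value, 1e-10)
  expect_lt(mean(em$emm$points$bv_mv[sc]), mean(em$emm$points$bv_mv[!sc]))
})

test_that("a wider configured UV gap increases the population AUC", {
  auc_for <- function(scar_uv_mean) {
    ep <- default_emm_params()
    ep$scar_mean[ep$param == "uv"] <- scar_uv_mean
    cfg <- lv_config(points_mean = 10000, points_sd = 0, points_min = 10000,
                     n_theta = 24, n_phi = 36, emm_params = ep)
    g <- generate_lv_geometry(cfg, 3)
    f <- generate_scar_field(g$endo_mesh_ed, cfg, 3)
    em <- sample_emm_map(g$endo_mesh_ed, f, cfg, 3)
    c_statistic(em$truth$scar_label, -em$emm$points$uv_mv)
  }
  aucs <- vapply(c(10, 8, 6), auc_for, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("cohort point count matches the mapping-density conditions", {
  cfg <- lv_config(n_theta = 24, n_phi = 36)
  study <- simulate_study(cfg)
  np <- vapply(study$subjects, function(s) nrow(s$emm$points), 0L)
  expect_true(all(np >= cfg$points_min))
  expect_gt(sum(np), 1100)  # ~13 x 112 = 1459 expected
  expect_lt(sum(np), 1900)
})

test_that("generated LGE slices carry consistent truth and realistic volume", {
  cfg <- lv_config()
  vols <- vapply(1:6, function(i) {
    sub_seed <- cfg$seed + i
    g <- generate_lv_geometry(cfg, sub_seed)
    f <- generate_scar_field(g$endo_mesh_ed, cfg, sub_seed)
    lge_infarct_volume(generate_lge_slices(g$slice_stack, f, cfg, sub_seed),
                       cfg$slice_thickness_mm)
  }, 0)
  expect_gt(mean(vols), 17.2 * 0.75)
  expect_lt(mean(vols), 17.2 * 1.25)
  # noiseless image: FWHM mask equals the pixel truth exactly
  cfg0 <- lv_config(lge_noise_sd = 0)
  g <- generate_lv_geometry(cfg0, 2)
  f <- generate_scar_field(g$endo_mesh_ed, cfg0, 2)
  lge <- generate_lge_slices(g$slice_stack, f, cfg0, 2)
  sl <- lge[[which.max(vapply(lge, function(s) sum(s$truth_scar), 0))]]
  mask <- fwhm_scar_mask(sl)
  expect_identical(unname(as.vector(mask)), as.vector(sl$truth_scar))
})
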