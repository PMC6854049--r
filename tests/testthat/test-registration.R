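make_cylinder_stack <- function(r = 25, zs = seq(0, 40, by = 5), n = 120) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  circ <- cbind(r * cos(a), r * sin(a))
  slices <- lapply(zs, function(z)
    list(z = z, endo_ed = circ, epi_ed = circ * 1.3,
         endo_es = circ, epi_es = circ * 1.3))
  structure(list(slices = slices, axis = c(0, 0, 1), slice_thickness_mm = 5),
            class = "contour_stack")
}

test_that("lofting circular contours yields a cylinder with a cap", {
  st <- make_cylinder_stack()
  mesh <- build_endo_mesh(st, "ED")
  analytic <- 2 * pi * 25 * 40 + pi * 25^2
  expect_lt(abs(mesh_surface_area(mesh) - analytic) / analytic, 0.02)
  expect_equal(mesh$vertices[mesh$apex_vertex, 3], 0)
  expect_equal(mesh$base_plane$point[3], 40)
  # fewer than 3 slices is a geometry error
  st1 <- st
  st1$slices <- st1$slices[1]
  expect_error(build_endo_mesh(st1), "at least 3 slices")
})

test_that("apex pre-alignment undoes a pure shift and keeps aligned data fixed", {
  g <- generate_lv_geometry(small_config(), 1)
  mesh <- g$endo_mesh_ed
  cloud <- as.data.frame(mesh$vertices)
  names(cloud) <- c("x_mm", "y_mm", "z_mm")
  shifted <- cloud
  shifted$x_mm <- shifted$x_mm + 5
  tf <- apex_prealign(shifted, mesh)
  expect_equal(tf$translation, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(rotation_angle_deg(tf), 0)
  tf0 <- apex_prealign(cloud, mesh)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_error(apex_prealign(cloud[rep(1, 10), ], mesh), "degenerate")
})

test_that("pre-alignment brings a misaligned synthetic cloud near the apex", {
  cfg <- small_config()
  sub <- simulate_subject(cfg, 1)
  mesh <- sub$geometry$endo_mesh_ed
  tf <- apex_prealign(sub$emm, mesh)
  moved <- apply_transform(tf, emm_positions(sub$emm))
  apex <- mesh$vertices[mesh$apex_vertex, ]
  d_apex <- min(sqrt(rowSums(sweep(moved, 2, apex)^2)))
  expect_lt(d_apex, max(1, 3 * cfg$noise_sd_mm))
})

test_that("ICP leaves an already-registered cloud essentially unmoved", {
  g <- generate_lv_geometry(small_config(), 2)
  set.seed(5)
  smp <- sample_mesh_surface(g$endo_mesh_ed, 150)
  df <- data.frame(x_mm = smp$points[, 1], y_mm = smp$points[, 2],
                   z_mm = smp$points[, 3])
  fit <- icp_constrained(df, g$endo_mesh_ed)
  expect_lt(fit$rms, 1e-6)
  expect_lt(rotation_angle_deg(fit$transform), 1e-3)
  expect_true(fit$converged)
  expect_error(icp_constrained(df[0, ], g$endo_mesh_ed), "no EMM points")
})

test_that("RMS trace is non-increasing and distances are rigid-invariant", {
  cfg <- small_config()
  sub <- simulate_subject(cfg, 2)
  mesh <- sub$geometry$endo_mesh_ed
  pre <- apex_prealign(sub$emm, mesh)
  pts <- apply_transform(pre, emm_positions(sub$emm))
  df <- data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
  fit <- icp_constrained(df, mesh, tol = 1e-5, max_iter = 40)
  expect_true(all(diff(fit$rms_trace) <= 1e-12))
  # applying one common rigid transform to cloud and mesh leaves the
  # point-to-surface distances unchanged
  tf <- rigid_transform(rotation_from_axis_angle(c(1, 1, 0), 30), c(5, -2, 7))
  mesh2 <- mesh
  mesh2$vertices <- apply_transform(tf, mesh$vertices)
  d1 <- closest_point_mesh(pts, mesh)$distance
  d2 <- closest_point_mesh(apply_transform(tf, pts), mesh2)$distance
  expect_lt(max(abs(d1 - d2)), 1e-6)
})

test_that("distance and basal exclusions follow the 5-mm and base-plane rules", {
  mesh <- emmscar:::build_spheroid_mesh(c(45, 29, 24), 120, 16, 24)
  pts <- data.frame(subject_id = 1,
                    x_mm = c(0, 0, 0), y_mm = c(0, 0, 0),
                    z_mm = c(-10, -20, 40))  # third is basal of z = 22.5
  ex <- exclude_points(pts, mesh, distances = c(1, 2, 6), max_dist_mm = 5)
  expect_equal(nrow(ex$retained), 2)
  expect_equal(ex$stats$mean_mm, 1.5)
  expect_equal(ex$stats$sd_mm, 0.7071, tolerance = 1e-4)
  expect_setequal(ex$excluded$exclusion_reason, "distance")
  ex2 <- exclude_points(pts, mesh, distances = c(1, 2, 2), max_dist_mm = 5)
  expect_equal(ex2$excluded$exclusion_reason, "basal")
  # conservation: retained + excluded = input, in all cases
  expect_equal(nrow(ex$retained) + nrow(ex$excluded), 3)
  expect_equal(nrow(ex2$retained) + nrow(ex2$excluded), 3)
  expect_warning(exclude_points(pts, mesh, distances = c(9, 9, 9)),
                 "all EMM points excluded")
})

test_that("full registration recovers the synthetic misalignment", {
  cfg <- lv_config(n_theta = 32, n_phi = 48, noise_sd_mm = 1)
  sub <- simulate_subject(cfg, 5)
  mesh <- build_endo_mesh(sub$geometry$slice_stack, "ED")
  reg <- register_emm(sub$emm, mesh, tol = 1e-5, max_iter = 60)
  expect_lte(rotation_angle_deg(reg$icp$transform), 10 + 1e-9)
  expect_lt(reg$stats$mean_mm, 3 * cfg$noise_sd_mm)
  expect_equal(nrow(reg$retained) + nrow(reg$excluded), nrow(sub$emm$points))
  # residual of (recovered o truth) should be small
  resid <- compose_transform(reg$transform, sub$truth$true_transform)
  expect_lt(rotation_angle_deg(resid), 4)
})
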