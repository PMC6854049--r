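#' Build an endocardial surface mesh from a contour stack
#'
#' Lofts successive short-axis contours into a triangulated surface and
#' closes the apical end with a flat fan cap; the apex vertex is the cap's
#' pole (the extremal long-axis vertex) and the base plane is the most
#' basal slice plane, with its normal pointing basally.
#'
#' @param contour_stack `contour_stack`.
#' @param phase `"ED"` or `"ES"`.
#' @param surface `"endo"` or `"epi"`.
#' @param n_phi resampled points per contour ring.
#' @return `surface_mesh`.
#' @export
build_endo_mesh <- function(contour_stack, phase = c("ED", "ES"),
                            surface = c("endo", "epi"), n_phi = 72) {
  phase <- match.arg(phase)
  surface <- match.arg(surface)
  key <- paste0(surface, if (phase == "ED") "_ed" else "_es")
  slices <- contour_stack$slices
  if (length(slices) < 3) stop("geometry error: need at least 3 slices")
  zs <- vapply(slices, function(s) s$z, 0)
  o <- order(zs)  # apex (minimum z) first
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  rings <- lapply(o, function(i) {
    poly <- slices[[i]][[key]]
    if (is.null(poly) || nrow(poly) < 3) stop("geometry error: missing contour")
    ctr <- polygon_centroid(poly)
    r <- polygon_radius(poly, ctr, ph)
    cbind(ctr[1] + r * cos(ph), ctr[2] + r * sin(ph), slices[[i]]$z)
  })
  # contours of successive slices must not cross: centroid shifts must stay
  # inside the smaller ring
  for (i in seq_len(length(rings) - 1)) {
    c1 <- colMeans(rings[[i]])[1:2]
    c2 <- colMeans(rings[[i + 1]])[1:2]
    if (sqrt(sum((c1 - c2)^2)) >
        min(max(dist_to_center(rings[[i]])), max(dist_to_center(rings[[i + 1]]))))
      stop("geometry error: crossing contours between slices")
  }
  apex_ctr <- colMeans(rings[[1]])
  verts <- rbind(c(apex_ctr[1:2], zs[o][1]), do.call(rbind, rings))
  vid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  jj <- seq_len(n_phi)
  faces <- cbind(1L, vid(1L, jj + 1L), vid(1L, jj))  # apical cap fan
  for (i in seq_len(length(rings) - 1L)) {
    a <- vid(i, jj); b <- vid(i, jj + 1L)
    c <- vid(i + 1L, jj + 1L); d <- vid(i + 1L, jj)
    faces <- rbind(faces, cbind(a, c, b), cbind(a, d, c))
  }
  base_ctr <- colMeans(rings[[length(rings)]])
  surface_mesh(verts, faces, apex_vertex = 1L,
               base_plane = list(point = base_ctr, normal = c(0, 0, 1)))
}

dist_to_center <- function(ring) {
  ctr <- colMeans(ring)
  sqrt((ring[, 1] - ctr[1])^2 + (ring[, 2] - ctr[2])^2)
}

#' Apex pre-registration of an EMM cloud to a mesh
#'
#' Finds the EMM cloud's apex as the extremal point along its principal
#' long axis, picking the extreme with the smaller transverse spread (the
#' apex is pointed, the base is wide), and returns the pure translation
#' that maps it onto the mesh apex vertex.
#'
#' @param emm `emm_map` (or data.frame with positions).
#' @param mesh `surface_mesh` with a valid `apex_vertex`.
#' @return `rigid_transform` with zero rotation.
#' @export
apex_prealign <- function(emm, mesh) {
  pts <- emm_positions(emm)
  if (nrow(pts) < 4 || max(apply(pts, 2, stats::sd)) < 1e-9)
    stop("registration error: degenerate EMM cloud")
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  axis1 <- pc$rotation[, 1]
  proj <- as.vector(sweep(pts, 2, ctr) %*% axis1)
  spread_at <- function(end_sign) {
    lim <- stats::quantile(end_sign * proj, 0.75)
    sel <- end_sign * proj >= lim
    perp <- sweep(pts[sel, , drop = FALSE], 2, ctr) -
      outer(proj[sel], axis1)
    mean(sqrt(rowSums(perp^2)))
  }
  apex_sign <- if (spread_at(1) < spread_at(-1)) 1 else -1
  emm_apex <- pts[which.max(apex_sign * proj), ]
  mesh_apex <- mesh$vertices[mesh$apex_vertex, ]
  rigid_transform(diag(3), mesh_apex - emm_apex)
}

#' Rotation-constrained iterative closest point registration
#'
#' Rigidly registers an EMM point cloud to a triangulated surface.  At each
#' iteration the closest point on the mesh surface (point-to-triangle) is
#' found for every EMM point, the best-fit rigid transform is computed, and
#' the cumulative rotation is clamped to `max_rotation_deg` about its own
#' axis whenever it exceeds the constraint (with the translation re-optimized
#' for the clamped rotation).  Iterations stop when the RMS point-to-surface
#' distance change falls below `tol`, when it would increase (the best
#' iterate is kept, so the RMS trace is non-increasing by construction), or
#' at `max_iter`.
#'
#' @param emm `emm_map` or position data.frame, already pre-aligned.
#' @param mesh `surface_mesh`.
#' @param max_rotation_deg rotation constraint (default 10).
#' @param tol RMS convergence tolerance (mm).
#' @param max_iter iteration cap.
#' @return list with `transform` (`rigid_transform`), `distances` (mm, per
#'   point, under the final transform), `rms`, `rms_trace`, `iterations`,
#'   `converged`.
#' @export
icp_constrained <- function(emm, mesh, max_rotation_deg = 10, tol = 1e-6,
                            max_iter = 100) {
  P0 <- emm_positions(emm)
  if (nrow(P0) == 0) stop("registration error: no EMM points")
  tf <- best_tf <- rigid_transform()
  rms_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    Q <- apply_transform(tf, P0)
    cp <- closest_point_mesh(Q, mesh)
    rms <- sqrt(mean(cp$distance^2))
    if (rms > rms_prev + 1e-12) {  # clamp can stall progress: keep best iterate
      tf <- best_tf
      converged <- TRUE
      break
    }
    trace <- c(trace, rms)
    best_tf <- tf
    iterations <- it
    if (rms_prev - rms < tol) { converged <- TRUE; break }
    rms_prev <- rms
    # best-fit rigid transform of the ORIGINAL points onto the current
    # correspondences; accumulates rotation so the clamp acts on the total
    cand <- kabsch_fit(P0, cp$closest)
    cand <- clamp_rotation(cand, max_rotation_deg)
    cand$translation <- colMeans(cp$closest) -
      as.vector(cand$rotation %*% colMeans(P0))
    tf <- cand
  }
  d_final <- closest_point_mesh(apply_transform(tf, P0), mesh)$distance
  list(transform = tf, distances = d_final,
       rms = sqrt(mean(d_final^2)), rms_trace = trace,
       iterations = iterations, converged = converged)
}

# least-squares rigid transform mapping X onto Y (SVD / Kabsch)
kabsch_fit <- function(X, Y) {
  xc <- colMeans(X)
  yc <- colMeans(Y)
  H <- crossprod(sweep(X, 2, xc), sweep(Y, 2, yc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, yc - as.vector(R %*% xc))
}

#' Distance and basal exclusion of registered EMM points
#'
#' Excludes points farther than `max_dist_mm` from the mesh surface and
#' points on the basal side of the mesh base plane (more basal than the
#' most basal MRI segmentation).  The registration error is reported as
#' mean and SD of the distances over the retained points only.
#'
#' @param emm `emm_map` with positions already under the final transform.
#' @param mesh `surface_mesh` with a `base_plane`.
#' @param distances per-point surface distances under the final transform.
#' @param max_dist_mm exclusion distance (default 5).
#' @return list with `retained`, `excluded` (data.frames with an
#'   `exclusion_reason` column), and `stats` (mean, sd, n over retained).
#' @export
exclude_points <- function(emm, mesh, distances, max_dist_mm = 5) {
  pts <- if (inherits(emm, "emm_map")) emm$points else emm
  pos <- emm_positions(pts)
  basal <- rep(FALSE, nrow(pos))
  if (!is.null(mesh$base_plane)) {
    bp <- mesh$base_plane
    basal <- as.vector(sweep(pos, 2, bp$point) %*% bp$normal) > 0
  }
  far <- distances > max_dist_mm
  pts$distance_mm <- distances
  pts$exclusion_reason <- ifelse(far, "distance", ifelse(basal, "basal", ""))
  excl <- far | basal
  retained <- pts[!excl, , drop = FALSE]
  stats <- if (nrow(retained) > 0)
    list(mean_mm = mean(retained$distance_mm),
         sd_mm = stats::sd(retained$distance_mm), n = nrow(retained))
  else {
    warning("all EMM points excluded; registration error undefined")
    list(mean_mm = NA_real_, sd_mm = NA_real_, n = 0L)
  }
  list(retained = retained, excluded = pts[excl, , drop = FALSE], stats = stats)
}

#' Register an EMM map to a mesh (apex pre-alignment + constrained ICP)
#'
#' Full registration stage: apex pre-alignment, rotation-constrained ICP,
#' application of the final transform and distance/basal exclusion.
#'
#' @param emm `emm_map`.
#' @param mesh `surface_mesh`.
#' @param max_rotation_deg,max_dist_mm,tol,max_iter see
#'   [icp_constrained()] and [exclude_points()].
#' @param init optional user-supplied initial `rigid_transform` replacing
#'   the automatic apex pre-alignment.
#' @return list with `transform` (total), `icp`, `prealign`, `retained`,
#'   `excluded`, `stats`.
#' @export
register_emm <- function(emm, mesh, max_rotation_deg = 10, max_dist_mm = 5,
                         tol = 1e-6, max_iter = 100, init = NULL) {
  pre <- if (is.null(init)) apex_prealign(emm, mesh) else init
  pts <- emm$points
  pre_pos <- apply_transform(pre, emm_positions(pts))
  pre_pts <- pts
  pre_pts[, c("x_mm", "y_mm", "z_mm")] <- pre_pos
  fit <- icp_constrained(pre_pts, mesh, max_rotation_deg = max_rotation_deg,
                         tol = tol, max_iter = max_iter)
  total <- compose_transform(fit$transform, pre)
  reg_pts <- pts
  reg_pts[, c("x_mm", "y_mm", "z_mm")] <- apply_transform(total, emm_positions(pts))
  ex <- exclude_points(reg_pts, mesh, fit$distances, max_dist_mm = max_dist_mm)
  list(transform = total, prealign = pre, icp = fit,
       retained = ex$retained, excluded = ex$excluded, stats = ex$stats)
}
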