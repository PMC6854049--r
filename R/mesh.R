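#' Triangulated LV surface mesh
#'
#' Container for a triangulated endocardial or epicardial surface in mm,
#' with optional named per-vertex scalar fields (e.g. `tm_pct`, `wt_mm`,
#' `wt_frac_pct`), the apex vertex index and the basal cutting plane.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param fields named list of length-n numeric vectors.
#' @param apex_vertex index of the apex vertex.
#' @param base_plane list with `point` and `normal` (normal points basally,
#'   away from the apex).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, fields = list(),
                         apex_vertex = NA_integer_, base_plane = NULL) {
  vertices <- matrix(as.numeric(as.matrix(vertices)), ncol = 3)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  for (f in fields) if (length(f) != nrow(vertices))
    stop("per-vertex field length must match vertex count")
  structure(list(vertices = vertices, faces = faces, fields = fields,
                 apex_vertex = apex_vertex, base_plane = base_plane),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, fields: %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (length(x$fields)) paste(names(x$fields), collapse = ", ") else "none"))
  invisible(x)
}

face_corners <- function(mesh) {
  list(A = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       B = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       C = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Face areas of a mesh
#' @param mesh `surface_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
mesh_face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  u <- fc$B - fc$A
  v <- fc$C - fc$A
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area
#' @param mesh `surface_mesh`.
#' @export
mesh_surface_area <- function(mesh) sum(mesh_face_areas(mesh))

#' Per-vertex barycentric area weights (one third of adjacent face areas)
#' @param mesh `surface_mesh`.
#' @export
mesh_vertex_areas <- function(mesh) {
  fa <- mesh_face_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    s <- rowsum(fa, mesh$faces[, k])
    va[as.integer(rownames(s))] <- va[as.integer(rownames(s))] + s[, 1]
  }
  va
}

#' Volume enclosed by the surface after capping the basal boundary
#'
#' Computes the signed volume by the divergence theorem, closing the open
#' basal boundary ring with a fan to its centroid.  Used to check synthetic
#' cavity volumes against physiological values.
#'
#' @param mesh `surface_mesh` whose only boundary is the basal ring.
#' @return volume in mm^3 (positive for outward orientation).
#' @export
mesh_enclosed_volume <- function(mesh) {
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
  faces <- mesh$faces
  verts <- mesh$vertices
  if (nrow(boundary) > 0) {
    ctr <- colMeans(verts[unique(as.vector(boundary)), , drop = FALSE])
    verts <- rbind(verts, ctr)
    ci <- nrow(verts)
    # boundary edges are oriented consistently with the faces they came from;
    # the cap triangle (b2, b1, ctr) closes the surface with matching winding
    cap <- cbind(boundary[, 2], boundary[, 1], ci)
    faces <- rbind(faces, cap)
  }
  A <- verts[faces[, 1], , drop = FALSE]
  B <- verts[faces[, 2], , drop = FALSE]
  C <- verts[faces[, 3], , drop = FALSE]
  v6 <- A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
    A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
    A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])
  abs(sum(v6)) / 6
}

#' Sample points uniformly by area on a mesh surface
#'
#' Triangles are drawn proportionally to area and points uniformly inside
#' each drawn triangle.  Draws from the current RNG stream.
#'
#' @param mesh `surface_mesh`.
#' @param n number of points.
#' @return list with `points` (n x 3), `face` (indices) and barycentric
#'   coordinates `bary` (n x 3).
#' @export
sample_mesh_surface <- function(mesh, n) {
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  fa <- mesh_face_areas(mesh)
  fi <- sample.int(length(fa), n, replace = TRUE, prob = fa)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  u <- 1 - r1
  v <- r1 * (1 - r2)
  w <- r1 * r2
  fc <- face_corners(mesh)
  pts <- u * fc$A[fi, , drop = FALSE] + v * fc$B[fi, , drop = FALSE] +
    w * fc$C[fi, , drop = FALSE]
  list(points = pts, face = fi, bary = cbind(u, v, w))
}

#' Intersect a mesh with a plane of constant z
#'
#' Returns the edge-crossing points of all faces with the plane `z = z0`;
#' used to check that slicing a generated mesh reproduces the contour stack.
#'
#' @param mesh `surface_mesh`.
#' @param z0 plane height (mm).
#' @return k x 3 matrix of intersection points (possibly empty).
#' @export
mesh_slice_points <- function(mesh, z0) {
  v <- mesh$vertices
  e <- unique(rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)]))
  z1 <- v[e[, 1], 3]
  z2 <- v[e[, 2], 3]
  cross <- (z1 - z0) * (z2 - z0) < 0
  if (!any(cross)) return(matrix(numeric(0), ncol = 3))
  t <- (z0 - z1[cross]) / (z2[cross] - z1[cross])
  v[e[cross, 1], , drop = FALSE] +
    t * (v[e[cross, 2], , drop = FALSE] - v[e[cross, 1], , drop = FALSE])
}

#' Closest points on a mesh surface for a set of query points
#'
#' Exact point-to-triangle projection, with a k-nearest-face-centroid
#' prefilter for speed.  This implements the registration-error definition:
#' the shortest distance of each EMM point to the closest point on the mesh
#' surface (not to the nearest vertex).
#'
#' @param points n x 3 query points.
#' @param mesh `surface_mesh`.
#' @param k number of candidate faces per query (prefilter size).
#' @return list with `closest` (n x 3) and `distance` (length n, mm).
#' @export
closest_point_mesh <- function(points, mesh, k = 64) {
  points <- matrix(as.numeric(points), ncol = 3)
  fc <- face_corners(mesh)
  cent <- (fc$A + fc$B + fc$C) / 3
  m <- nrow(cent)
  k <- as.integer(min(k, m))
  n <- nrow(points)
  # k nearest face centroids per query point (candidate prefilter)
  cand <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2c <- (cent[, 1] - points[i, 1])^2 + (cent[, 2] - points[i, 2])^2 +
      (cent[, 3] - points[i, 3])^2
    cand[i, ] <- if (k < m) {
      kth <- sort(d2c, partial = k)[k]
      which(d2c <= kth)[seq_len(k)]
    } else seq_len(m)
  }
  ci <- as.vector(t(cand))            # nk face indices, point-major
  pi_ <- rep(seq_len(n), each = k)
  P <- points[pi_, , drop = FALSE]
  cp <- closest_point_triangles(P, fc$A[ci, , drop = FALSE],
                                fc$B[ci, , drop = FALSE],
                                fc$C[ci, , drop = FALSE])
  d2 <- (cp[, 1] - P[, 1])^2 + (cp[, 2] - P[, 2])^2 + (cp[, 3] - P[, 3])^2
  best <- vapply(seq_len(n), function(i)
    (i - 1L) * k + which.min(d2[((i - 1L) * k + 1L):(i * k)]), integer(1))
  best <- as.integer(best)
  list(closest = cp[best, , drop = FALSE], distance = sqrt(d2[best]))
}

# Closest point on each triangle (rows of A,B,C) to the matching row of P.
# Standard Voronoi-region case analysis (Ericson), fully vectorized.
closest_point_triangles <- function(P, A, B, C) {
  ab <- B - A
  ac <- C - A
  ap <- P - A
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp_ <- P - C
  d5 <- rowSums(ab * cp_)
  d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(A)
  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_rows <- function(idx, val) {
    if (any(idx)) res[idx, ] <<- val[idx, , drop = FALSE]
    done <<- done | idx
  }
  set_rows(!done & d1 <= 0 & d2 <= 0, A)                     # vertex A
  set_rows(!done & d3 >= 0 & d4 <= d3, B)                    # vertex B
  set_rows(!done & d6 >= 0 & d5 <= d6, C)                    # vertex C
  vv <- d1 / (d1 - d3)
  set_rows(!done & vc <= 0 & d1 >= 0 & d3 <= 0, A + vv * ab) # edge AB
  ww <- d2 / (d2 - d6)
  set_rows(!done & vb <= 0 & d2 >= 0 & d6 <= 0, A + ww * ac) # edge AC
  uu <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_rows(!done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
           B + uu * (C - B))                                 # edge BC
  denom <- 1 / (va + vb + vc)
  v <- vb * denom
  w <- vc * denom
  if (any(!done)) res[!done, ] <- (A + v * ab + w * ac)[!done, , drop = FALSE]
  res
}

#' Write a mesh to ASCII PLY
#'
#' Per-vertex fields are written as extra float vertex properties so scalar
#' maps (transmurality, wall thickening) travel with the geometry.
#'
#' @param mesh `surface_mesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  nf <- names(mesh$fields)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("property float %s", nf),
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  vm <- mesh$vertices
  for (f in nf) vm <- cbind(vm, mesh$fields[[f]])
  vl <- apply(vm, 1, function(r) paste(format(r, trim = TRUE, digits = 9), collapse = " "))
  fl <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()]
#' @param path PLY file.
#' @return `surface_mesh` (fields restored, apex/base plane not stored in PLY).
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "ply") stop("not a PLY file")
  end <- which(ln == "end_header")[1]
  hdr <- ln[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nfc <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  props <- sub("property float ", "", grep("^property float", hdr, value = TRUE))
  vdat <- utils::read.table(text = ln[(end + 1):(end + nv)], col.names = props)
  fdat <- utils::read.table(text = ln[(end + nv + 1):(end + nv + nfc)])
  fields <- list()
  for (f in setdiff(props, c("x", "y", "z"))) fields[[f]] <- vdat[[f]]
  surface_mesh(as.matrix(vdat[, c("x", "y", "z")]), as.matrix(fdat[, 2:4]) + 1L,
               fields = fields)
}
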