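# Planar polygon helpers shared by the LGE quantification and the
# synthetic image generator.  Polygons are k x 2 matrices of closed
# (implicitly wrapped) contours in mm.

#' Even-odd point-in-polygon test
#' @param x,y point coordinates (vectors).
#' @param poly k x 2 polygon vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    denom <- yj - yi
    if (denom != 0) {
      cross <- ((yi > y) != (yj > y)) & (x < (xj - xi) * (y - yi) / denom + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Signed area of a polygon (shoelace)
#' @param poly k x 2 matrix.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of a polygon
#' @param poly k x 2 matrix.
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Radius of a star-shaped polygon at given angles
#'
#' Interpolates the polygon's radius-versus-angle profile about `center`;
#' valid for contours that are star-shaped about that point (LV short-axis
#' contours about the cavity centroid).
#'
#' @param poly k x 2 matrix.
#' @param center length-2 reference point.
#' @param angles query angles (radians, from +x counterclockwise).
#' @return radii (mm) at the query angles.
#' @export
polygon_radius <- function(poly, center, angles) {
  dx <- poly[, 1] - center[1]
  dy <- poly[, 2] - center[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(ang)
  ang <- ang[o]; r <- r[o]
  # wrap for circular interpolation
  ang <- c(ang[length(ang)] - 2 * pi, ang, ang[1] + 2 * pi)
  r <- c(r[length(r) - 0], r, r[1])
  stats::approx(ang, r, xout = angles %% (2 * pi), rule = 2)$y
}
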