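#' Rigid transforms in 3-D
#'
#' A rigid transform is stored as a proper 3x3 rotation matrix plus a
#' translation vector in mm, and applied as `x -> R x + t`.  Rotations are
#' reported to the user in axis-angle form (degrees), the convention used
#' for the 10-degree rotation constraint during EMM-to-mesh registration.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("rotation must be a proper rotation matrix (no reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Build a rotation matrix from axis-angle form
#'
#' @param axis rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("axis must be non-zero")
  a <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Decompose a rotation matrix into axis-angle form
#'
#' @param R 3x3 rotation matrix.
#' @return list with `axis` (unit vector) and `angle_deg` (in \[0, 180\]).
#' @export
rotation_to_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cth <- min(1, max(-1, (tr - 1) / 2))
  th <- acos(cth)
  if (th < 1e-12) return(list(axis = c(0, 0, 1), angle_deg = 0))
  if (pi - th < 1e-6) {
    # angle ~ 180 deg: recover axis from the symmetric part
    B <- (R + diag(3)) / 2
    d <- sqrt(pmax(diag(B), 0))
    i <- which.max(d)
    ax <- B[, i] / d[i]
    ax <- ax / sqrt(sum(ax^2))
    return(list(axis = ax, angle_deg = th * 180 / pi))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  list(axis = ax / sqrt(sum(ax^2)), angle_deg = th * 180 / pi)
}

#' Rotation angle of a transform in degrees
#' @param tf `rigid_transform`.
#' @export
rotation_angle_deg <- function(tf) rotation_to_axis_angle(tf$rotation)$angle_deg

#' Apply a rigid transform to a point matrix
#' @param tf `rigid_transform`.
#' @param points n x 3 matrix of positions (mm).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(tf, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Compose two rigid transforms
#' @param tf2,tf1 `rigid_transform`s; the result applies `tf1` first.
#' @export
compose_transform <- function(tf2, tf1) {
  rigid_transform(tf2$rotation %*% tf1$rotation,
                  as.numeric(tf2$rotation %*% tf1$translation) + tf2$translation)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tf$translation))
}

#' Clamp the rotation angle of a transform
#'
#' Projects the rotation onto the feasible set of the registration's
#' rotation constraint: if the total rotation angle exceeds `max_deg` it is
#' reduced to `max_deg` about the same axis; the translation is untouched.
#'
#' @param tf `rigid_transform`.
#' @param max_deg maximum allowed rotation angle (degrees).
#' @export
clamp_rotation <- function(tf, max_deg) {
  aa <- rotation_to_axis_angle(tf$rotation)
  if (aa$angle_deg <= max_deg) return(tf)
  rigid_transform(rotation_from_axis_angle(aa$axis, max_deg), tf$translation)
}

#' Random rigid transform
#'
#' Uniform random axis, rotation angle uniform on \[0, `max_rot_deg`\] and a
#' translation uniform in the ball of radius `max_trans_mm`.  Draws from the
#' current RNG stream.
#'
#' @param max_rot_deg,max_trans_mm bounds for the draw.
#' @export
random_rigid_transform <- function(max_rot_deg, max_trans_mm) {
  ax <- stats::rnorm(3)
  tr <- stats::rnorm(3)
  tr <- tr / sqrt(sum(tr^2)) * max_trans_mm * stats::runif(1)^(1 / 3)
  rigid_transform(rotation_from_axis_angle(ax, stats::runif(1, 0, max_rot_deg)), tr)
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_to_axis_angle(x$rotation)
  cat(sprintf("rigid transform: rotation %.3f deg about [%.3f, %.3f, %.3f], translation [%.3f, %.3f, %.3f] mm\n",
              aa$angle_deg, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Serialize a transform to a JSON-ready list (axis-angle degrees + mm)
#' @param tf `rigid_transform`.
#' @export
transform_to_list <- function(tf) {
  aa <- rotation_to_axis_angle(tf$rotation)
  list(axis = aa$axis, angle_deg = aa$angle_deg, translation_mm = tf$translation)
}

#' Rebuild a transform from `transform_to_list()` output
#' @param x list with `axis`, `angle_deg`, `translation_mm`.
#' @export
transform_from_list <- function(x) {
  rigid_transform(rotation_from_axis_angle(unlist(x$axis), x$angle_deg),
                  unlist(x$translation_mm))
}
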