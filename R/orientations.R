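## Orientations are unit quaternions (qw, qx, qy, qz), active rotation of the
## object, right-handed; snapshots are projections along the laboratory z axis.
## q and -q describe the same rotation.

#' Quaternion to rotation matrix
#'
#' Converts a unit quaternion (w, x, y, z) to the 3x3 active rotation matrix.
#'
#' @param q numeric length-4 vector, unit norm.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  check_unit_quaternion(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

## Quaternion for rotation by `angle` about unit `axis`.
axis_angle_quat <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop_confmap("rotation axis must be a non-zero vector")
  a <- axis / nrm
  c(cos(angle / 2), sin(angle / 2) * a)
}

check_unit_quaternion <- function(q, tol = 1e-6) {
  if (length(q) != 4 || abs(sqrt(sum(q^2)) - 1) > tol)
    stop_confmap("orientation must be a unit quaternion (|q| = 1 within %g)", tol)
  invisible(TRUE)
}

#' Sample snapshot orientations
#'
#' Draws `n` orientations either Haar-uniformly over SO(3) (`uniform_so3`) or
#' as `n` equally spaced rotations about a fixed axis (`single_axis`), the two
#' acquisition geometries used for full three-dimensional and tilt-series-like
#' synthetic datasets.
#'
#' @param n number of orientations.
#' @param mode `"uniform_so3"` or `"single_axis"`.
#' @param axis rotation axis for `single_axis` (default z).
#' @param seed integer seed; draws are reproducible under it.
#' @return an `n x 4` matrix of unit quaternions (rows `qw,qx,qy,qz`).
#' @export
sample_orientations <- function(n, mode = c("uniform_so3", "single_axis"),
                                axis = c(0, 0, 1), seed = 1L) {
  mode <- match.arg(mode)
  if (n < 1) stop_confmap("n must be >= 1")
  if (mode == "uniform_so3") {
    set.seed(as.integer(seed))
    ## normalized 4D Gaussians are Haar-uniform on S^3
    q <- matrix(rnorm(4 * n), ncol = 4)
    q <- q / sqrt(rowSums(q^2))
  } else {
    angles <- 2 * pi * (seq_len(n) - 1) / n
    q <- t(vapply(angles, function(a) axis_angle_quat(axis, a), numeric(4)))
  }
  colnames(q) <- c("qw", "qx", "qy", "qz")
  q
}

#' Viewing axis of an orientation
#'
#' The projection direction expressed in the object frame: the laboratory z
#' axis pulled back through the (active) object rotation.
#'
#' @param q unit quaternion.
#' @return unit length-3 vector.
#' @export
viewing_axis <- function(q) {
  R <- quat_to_matrix(q)
  ## projecting the rotated object along lab z == projecting the object along
  ## R^T z, so the viewing direction in the object frame is the third row of R
  as.numeric(R[3, ])
}

#' Great-circle angular distance between viewing directions
#'
#' The angle, in \[0, pi\], between the viewing axes of two orientations on the
#' unit sphere.  In-plane rotation about the beam is ignored: two snapshots
#' taken along the same direction but rotated in the detector plane are at
#' angular distance zero.
#'
#' @param q_i,q_j unit quaternions.
#' @return angle in radians.
#' @export
great_circle_distance <- function(q_i, q_j) {
  a <- viewing_axis(q_i); b <- viewing_axis(q_j)
  acos(max(-1, min(1, sum(a * b))))
}

## Pairwise great-circle distances for an n x 4 quaternion matrix: n x n.
viewing_axes <- function(quaternions) {
  t(apply(quaternions, 1, viewing_axis))
}

pairwise_viewing_angles <- function(quaternions) {
  ax <- viewing_axes(quaternions)
  g <- tcrossprod(ax)
  g[g > 1] <- 1; g[g < -1] <- -1
  acos(g)
}

#' Shannon (Crowther) angle
#'
#' The angular sampling increment `resolution / diameter` for a particle of
#' the given diameter imaged to the given resolution, in radians.  The
#' orientation gate of the conformational kernel is conventionally set to two
#' Shannon angles.
#'
#' @param particle_diameter particle diameter (any length unit).
#' @param resolution target resolution (same unit).
#' @return angle in radians.
#' @export
shannon_angle <- function(particle_diameter, resolution) {
  if (particle_diameter <= 0 || resolution <= 0)
    stop_confmap("particle_diameter and resolution must be positive")
  resolution / particle_diameter
}
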