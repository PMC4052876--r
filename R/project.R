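## Parallel-beam projection of a phantom along the laboratory z axis after an
## active rotation of the object.  Two routes:
##   * analytic  — the line integral of a rotated isotropic Gaussian blob is a
##     2D Gaussian of the same width centred at the rotated blob position,
##     with integrated weight w * sigma * sqrt(2*pi); exact and fast.
##   * grid      — rotate the voxel grid by trilinear resampling and sum
##     along z (times voxel_size); the generic line-integral discretization,
##     used to cross-check the analytic path and for phantoms supplied as
##     plain volumes.

#' Project a phantom along the beam
#'
#' Computes the 2D parallel projection of the (rotated) phantom density on a
#' detector grid matching the phantom grid (same side length, pixel size =
#' voxel size).  Linear in the density.
#'
#' @param phantom a [make_phantom()] object.
#' @param orientation unit quaternion (active rotation of the object).
#' @param method `"analytic"` (closed-form blob projection, default when the
#'   blob table is available) or `"grid"` (rotate + z-sum of the voxel grid).
#' @return a `grid_size x grid_size` numeric matrix (density * length units).
#' @export
project <- function(phantom, orientation, method = c("analytic", "grid")) {
  stopifnot(inherits(phantom, "phantom"))
  method <- match.arg(method)
  check_unit_quaternion(orientation)
  if (method == "analytic") {
    if (is.null(phantom$blobs)) stop_confmap("phantom has no blob table; use method = 'grid'")
    project_blobs(phantom$blobs, quat_to_matrix(orientation),
                  phantom$grid_size, phantom$voxel_size)
  } else {
    if (is.null(phantom$voxel_grid))
      stop_confmap("phantom grid not rendered; rebuild with build_grid = TRUE")
    project_grid(phantom$voxel_grid, quat_to_matrix(orientation), phantom$voxel_size)
  }
}

project_blobs <- function(blobs, R, n, pixel_size) {
  xy <- grid_coords(n, pixel_size)
  img <- matrix(0, n, n)
  centres <- R %*% rbind(blobs$x, blobs$y, blobs$z)   # active rotation
  for (i in seq_len(nrow(blobs))) {
    s <- blobs$sigma[i]
    amp <- blobs$weight[i] * s * sqrt(2 * pi)
    gx <- exp(-(xy - centres[1, i])^2 / (2 * s^2))
    gy <- exp(-(xy - centres[2, i])^2 / (2 * s^2))
    img <- img + amp * (gx %o% gy)
  }
  img
}

project_grid <- function(vol, R, voxel_size) {
  n <- dim(vol)[1]
  if (length(unique(dim(vol))) != 1) stop_confmap("voxel grid must be cubic")
  g <- grid_coords(n, voxel_size)
  ## rotated density at X is density(R^-1 X); build R^-1 X for all voxels
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  src <- pts %*% R            # (R^T X)^T rows == R^-1 applied to each point
  rot <- array(trilinear_interp(vol, src, g), dim = c(n, n, n))
  apply(rot, c(1, 2), sum) * voxel_size
}

## Vectorized trilinear interpolation of a cubic volume at arbitrary points
## (coordinates in the same physical units as grid `g`); zero outside.
trilinear_interp <- function(vol, pts, g) {
  n <- length(g)
  step <- g[2] - g[1]
  ## fractional voxel index of each point
  fi <- (pts - g[1]) / step + 1
  i0 <- floor(fi)
  fr <- fi - i0
  ok <- i0[, 1] >= 1 & i0[, 1] < n & i0[, 2] >= 1 & i0[, 2] < n &
        i0[, 3] >= 1 & i0[, 3] < n
  out <- numeric(nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fr <- fr[ok, , drop = FALSE]
  idx <- function(dx, dy, dz)
    (i0[, 1] + dx) + n * (i0[, 2] + dy - 1) + n * n * (i0[, 3] + dz - 1)
  v <- vol
  dim(v) <- NULL
  wx0 <- 1 - fr[, 1]; wy0 <- 1 - fr[, 2]; wz0 <- 1 - fr[, 3]
  out[ok] <-
    v[idx(0, 0, 0)] * wx0 * wy0 * wz0 +
    v[idx(1, 0, 0)] * fr[, 1] * wy0 * wz0 +
    v[idx(0, 1, 0)] * wx0 * fr[, 2] * wz0 +
    v[idx(1, 1, 0)] * fr[, 1] * fr[, 2] * wz0 +
    v[idx(0, 0, 1)] * wx0 * wy0 * fr[, 3] +
    v[idx(1, 0, 1)] * fr[, 1] * wy0 * fr[, 3] +
    v[idx(0, 1, 1)] * wx0 * fr[, 2] * fr[, 3] +
    v[idx(1, 1, 1)] * fr[, 1] * fr[, 2] * fr[, 3]
  out
}
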