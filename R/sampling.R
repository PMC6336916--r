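## Trilinear sampling of scalar volumes at surface-defined points.

#' Sample a volume at world-coordinate points
#'
#' Trilinear interpolation of an `fcd_volume` at arbitrary RAS points.
#' Points whose 8-voxel support leaves the array are masked `NA` (never
#' clamped, so edge artifacts cannot leak in silently). Trilinear sampling
#' is exact for intensity fields affine in the world coordinates and is
#' linear in the volume.
#'
#' @param volume an `fcd_volume`.
#' @param points N x 3 matrix of RAS coordinates in mm.
#' @param method `"trilinear"` or `"nearest"` (for label volumes).
#' @return numeric vector of length N with `NA` for out-of-bounds points.
#' @export
sample_volume <- function(volume, points, method = c("trilinear", "nearest")) {
  stopifnot(inherits(volume, "fcd_volume"))
  method <- match.arg(method)
  points <- as.matrix(points)
  inv <- solve(volume$affine)
  vox <- cbind(points, 1) %*% t(inv)  # continuous 0-based voxel coords
  d <- dim(volume$data)
  if (method == "nearest") {
    ijk <- round(vox[, 1:3, drop = FALSE]) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    out <- rep(NA_real_, nrow(points))
    out[ok] <- volume$data[ijk[ok, , drop = FALSE]]
    return(out)
  }
  f <- floor(vox[, 1:3, drop = FALSE])
  t_ <- vox[, 1:3, drop = FALSE] - f
  i0 <- f + 1  # 1-based lower corner
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 & i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
    i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  i0k <- i0[ok, , drop = FALSE]
  tk <- t_[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tk[, 1] else 1 - tk[, 1]) *
      (if (dy) tk[, 2] else 1 - tk[, 2]) *
      (if (dz) tk[, 3] else 1 - tk[, 3])
    idx <- cbind(i0k[, 1] + dx, i0k[, 2] + dy, i0k[, 3] + dz)
    acc <- acc + w * volume$data[idx]
  }
  out[ok] <- acc
  out
}

#' Sample a volume at a fractional cortical depth
#'
#' For each vertex i, samples the volume at
#' `white_i + fraction * (pial_i - white_i)`: fraction 0 is the GM/WM
#' boundary, 1 the pial surface.
#'
#' @param volume an `fcd_volume` co-registered with the surfaces.
#' @param pair an `fcd_surface_pair`.
#' @param fraction cortical depth fraction in `[0, 1]`.
#' @param method interpolation method, see [sample_volume()].
#' @return an `fcd_scalar_map`; out-of-volume samples are `NA`.
#' @export
sample_at_fraction <- function(volume, pair, fraction,
                               method = c("trilinear", "nearest")) {
  stopifnot(inherits(pair, "fcd_surface_pair"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  pts <- pair$white$vertices +
    fraction * (pair$pial$vertices - pair$white$vertices)
  scalar_map(sample_volume(volume, pts, method = method),
             sprintf("depth_%g", fraction), "intensity")
}

#' Sample a volume below the GM/WM boundary
#'
#' Samples at `white_i - depth_mm * n_i`, where `n_i` is the white-surface
#' outward unit normal, i.e. at a fixed distance inside the white matter.
#'
#' @param volume an `fcd_volume`.
#' @param pair an `fcd_surface_pair`.
#' @param depth_mm sampling depth below the boundary in mm (> 0).
#' @param method interpolation method, see [sample_volume()].
#' @return an `fcd_scalar_map`; out-of-volume samples are `NA`.
#' @export
sample_below_white <- function(volume, pair, depth_mm,
                               method = c("trilinear", "nearest")) {
  stopifnot(inherits(pair, "fcd_surface_pair"))
  if (!is.numeric(depth_mm) || depth_mm <= 0) stop("depth_mm must be > 0")
  pts <- pair$white$vertices - depth_mm * pair$white$vertex_normals
  scalar_map(sample_volume(volume, pts, method = method),
             sprintf("below_white_%gmm", depth_mm), "intensity")
}
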