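#' Subdivided icosahedron on the unit sphere
#'
#' Generates the standard icosphere by repeated 4-way subdivision of an
#' icosahedron with all vertices projected back to the unit sphere. Faces are
#' wound counterclockwise seen from outside, so mesh normals point outward.
#' Used as the base topology of the synthetic hemispheres and as an analytic
#' fixture (a sphere of radius R has mean curvature 1/R and Gaussian
#' curvature 1/R^2).
#'
#' @param subdivisions non-negative integer; vertex count is
#'   `10 * 4^subdivisions + 2` (0 -> 12, 3 -> 642, 4 -> 2562).
#' @return list with `vertices` (unit norm) and `faces`.
#' @export
icosphere <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    n <- nrow(v)
    edges <- unique(rbind(
      cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
      cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
    mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    key <- (edges[, 1] - 1) * n + edges[, 2]
    lookup <- function(a, b) {
      k <- (pmin(a, b) - 1) * n + pmax(a, b)
      n + match(k, key)
    }
    m12 <- lookup(f[, 1], f[, 2])
    m23 <- lookup(f[, 2], f[, 3])
    m31 <- lookup(f[, 3], f[, 1])
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    v <- rbind(v, mid)
  }
  list(vertices = v, faces = f)
}

#' Flat triangulated grids
#'
#' Planar calibration meshes in the z = 0 plane. `grid_mesh()` triangulates a
#' regular square lattice (right triangles); `tri_grid_mesh()` builds an
#' equilateral-triangle lattice, whose isotropic vertex stars make it the
#' reference mesh for smoothing-kernel calibration checks.
#'
#' @param nx,ny lattice size (number of vertices per side).
#' @param spacing lattice spacing in mm.
#' @return list with `vertices` (N x 3, z = 0) and `faces` (CCW seen from +z).
#' @export
grid_mesh <- function(nx = 20, ny = 20, spacing = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind((g$x - (nx + 1) / 2) * spacing, (g$y - (ny + 1) / 2) * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    f <- rbind(f,
               cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
               cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  list(vertices = v, faces = f)
}

#' @rdname grid_mesh
#' @export
tri_grid_mesh <- function(nx = 20, ny = 20, spacing = 1) {
  h <- spacing * sqrt(3) / 2
  rows <- lapply(seq_len(ny), function(j) {
    x <- (seq_len(nx) - 1) * spacing + if (j %% 2 == 0) spacing / 2 else 0
    cbind(x, (j - 1) * h, 0)
  })
  v <- do.call(rbind, rows)
  v[, 1] <- v[, 1] - mean(range(v[, 1]))
  v[, 2] <- v[, 2] - mean(range(v[, 2]))
  idx <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    if (j %% 2 == 1) {
      f <- rbind(f,
                 cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
                 cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    } else {
      f <- rbind(f,
                 cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    }
  }
  list(vertices = v, faces = f)
}
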