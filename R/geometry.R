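#' Geodesic neighborhood of a vertex
#'
#' All vertices whose shortest-path distance to `center` along mesh edges
#' (Dijkstra on the edge-length graph) is at most `radius`, with distances.
#' The center itself is always included at distance 0. Edge-graph distances
#' slightly overestimate exact polyhedral geodesics; at the neighborhood
#' scales used here (6 mm doughnuts, 25 mm curvature rings) the bias is
#' negligible relative to mesh resolution.
#'
#' @param mesh an `fcd_mesh`.
#' @param center vertex index (1-based).
#' @param radius neighborhood radius in mm (> 0).
#' @return data.frame with columns `vertex` and `distance`, ordered by
#'   vertex index.
#' @export
geodesic_neighborhood <- function(mesh, center, radius) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  n <- nrow(mesh$vertices)
  center <- as.integer(center)
  if (length(center) != 1L || is.na(center) || center < 1L || center > n)
    stop("center vertex index out of range [1, ", n, "]")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  g <- .mesh_csr(mesh)
  res <- .cpp_geodesic_disc(n, g$off, g$adj, g$w, center - 1L, radius)
  data.frame(vertex = res$vertex, distance = res$distance)
}

## distance from every vertex to the nearest of `sources` (1-based)
.geodesic_multisource <- function(mesh, sources) {
  g <- .mesh_csr(mesh)
  .cpp_geodesic_multisource(nrow(mesh$vertices), g$off, g$adj, g$w,
                            as.integer(sources) - 1L)
}

## per-vertex disc/annulus area-weighted means for one or more maps
.disc_annulus_stats <- function(mesh, values, r_disc, r_outer) {
  g <- .mesh_csr(mesh)
  vals <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  .cpp_disc_annulus_stats(nrow(mesh$vertices), g$off, g$adj, g$w,
                          vals, mesh$vertex_areas, r_disc, r_outer)
}

## cotangent edge weights w_ij = (cot a + cot b)/2 over incident faces.
## Negative contributions (obtuse triangles) are clamped to zero so that the
## diffusion operator keeps the discrete maximum principle.
.cot_weights <- function(mesh, clamp = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  ii <- jj <- integer(0)
  ww <- numeric(0)
  for (k in 1:3) {
    opp <- f[, k]
    a <- f[, if (k == 3) 1 else k + 1]
    b <- f[, if (k == 1) 3 else k - 1]
    u1 <- v[a, , drop = FALSE] - v[opp, , drop = FALSE]
    u2 <- v[b, , drop = FALSE] - v[opp, , drop = FALSE]
    dt <- rowSums(u1 * u2)
    cr <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
                u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
                u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
    crn <- sqrt(rowSums(cr^2))
    cot <- ifelse(crn > 1e-12, dt / crn, 0)
    ii <- c(ii, a)
    jj <- c(jj, b)
    ww <- c(ww, cot / 2)
  }
  key <- paste(pmin(ii, jj), pmax(ii, jj))
  w <- rowsum(ww, key)
  pieces <- do.call(rbind, strsplit(rownames(w), " ", fixed = TRUE))
  wij <- w[, 1L]
  if (clamp) wij <- pmax(wij, 0)
  list(i = as.integer(pieces[, 1L]), j = as.integer(pieces[, 2L]), w = wij)
}

## Voronoi "mixed" vertex areas (Meyer et al.): cotangent Voronoi area in
## non-obtuse triangles, A/2 at the obtuse corner and A/4 elsewhere in
## obtuse ones. Used to normalize the curvature estimators, where the
## barycentric one-third areas leave a persistent bias at irregular
## vertices; the mesh's partition-of-unity areas stay barycentric.
.mixed_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  e <- list(v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE],
            v[f[, 1], , drop = FALSE] - v[f[, 3], , drop = FALSE],
            v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  l2 <- vapply(e, function(x) rowSums(x^2), numeric(nrow(f)))
  cr <- cbind(e[[1]][, 2] * e[[2]][, 3] - e[[1]][, 3] * e[[2]][, 2],
              e[[1]][, 3] * e[[2]][, 1] - e[[1]][, 1] * e[[2]][, 3],
              e[[1]][, 1] * e[[2]][, 2] - e[[1]][, 2] * e[[2]][, 1])
  area2 <- sqrt(rowSums(cr^2))          # 2 * face area
  cot <- matrix(0, nrow(f), 3L)         # cot of angle at vertex k
  for (k in 1:3) {
    a <- (k %% 3) + 1L; b <- ((k + 1L) %% 3) + 1L
    cot[, k] <- -rowSums(e[[a]] * e[[b]]) / pmax(area2, 1e-300)
  }
  obtuse_at <- max.col(-cot * (cot < 0), ties.method = "first")
  any_obtuse <- rowSums(cot < 0) > 0L
  out <- numeric(n)
  for (k in 1:3) {
    a <- (k %% 3) + 1L; b <- ((k + 1L) %% 3) + 1L
    voronoi <- (l2[, a] * cot[, a] + l2[, b] * cot[, b]) / 8
    contrib <- ifelse(!any_obtuse, voronoi,
                      ifelse(obtuse_at == k, area2 / 4, area2 / 8))
    out <- out + .accumulate(f[, k], contrib, n)
  }
  out
}

#' Discrete mean curvature
#'
#' Signed mean curvature per vertex from the cotangent-Laplacian estimator
#' of the mean-curvature normal. Sign convention: with outward normals from
#' counterclockwise winding, concave regions (sulcal fundi) are positive and
#' convex regions (gyral crowns, a sphere) are negative; reversing the face
#' orientation flips the sign. Boundary vertices, where the one-ring is
#' incomplete, are masked `NA`.
#'
#' @param mesh an `fcd_mesh`.
#' @return an `fcd_scalar_map` in 1/mm.
#' @export
mean_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  v <- mesh$vertices
  n <- nrow(v)
  cw <- .cot_weights(mesh, clamp = FALSE)
  # mean-curvature normal K_i = (1/(2A_i)) sum_j (cot a + cot b)(v_i - v_j)
  kv <- matrix(0, n, 3L)
  for (k in 1:3) {
    d <- v[cw$i, k] - v[cw$j, k]
    kv[, k] <- kv[, k] + .accumulate(cw$i, 2 * cw$w * d, n) +
      .accumulate(cw$j, -2 * cw$w * d, n)
  }
  kv <- kv / (2 * .mixed_areas(mesh))
  h <- -rowSums(kv * mesh$vertex_normals) / 2
  h[mesh$boundary] <- NA_real_
  scalar_map(h, "mean_curvature", "1/mm")
}

#' Discrete Gaussian curvature
#'
#' Angle-deficit (Gauss-Bonnet) estimate: `(2*pi - sum of incident face
#' angles) / vertex area`. Summed against vertex areas over a closed mesh
#' this reproduces `2*pi*chi` (Euler characteristic) exactly. Boundary
#' vertices are masked `NA`.
#'
#' @param mesh an `fcd_mesh`.
#' @return an `fcd_scalar_map` in 1/mm^2.
#' @export
gaussian_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  total <- numeric(n)
  for (k in 1:3) {
    at <- f[, k]
    a <- f[, if (k == 3) 1 else k + 1]
    b <- f[, if (k == 1) 3 else k - 1]
    u1 <- v[a, , drop = FALSE] - v[at, , drop = FALSE]
    u2 <- v[b, , drop = FALSE] - v[at, , drop = FALSE]
    n1 <- sqrt(rowSums(u1^2))
    n2 <- sqrt(rowSums(u2^2))
    ok <- n1 > 1e-12 & n2 > 1e-12
    cosang <- rep(1, length(at))
    cosang[ok] <- pmin(1, pmax(-1, rowSums(u1 * u2)[ok] / (n1[ok] * n2[ok])))
    total <- total + .accumulate(at, acos(cosang), n)
  }
  kk <- (2 * pi - total) / .mixed_areas(mesh)
  kk[mesh$boundary] <- NA_real_
  scalar_map(kk, "gaussian_curvature", "1/mm^2")
}

## Uniform Laplacian mesh smoothing of vertex coordinates (used for the
## smoothed pial envelope and the synthetic inflated surface).
.smooth_coordinates <- function(mesh, iterations, lambda = 1) {
  v <- mesh$vertices
  n <- nrow(v)
  W <- Matrix::sparseMatrix(
    i = c(mesh$edges[, 1L], mesh$edges[, 2L]),
    j = c(mesh$edges[, 2L], mesh$edges[, 1L]),
    x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(W)
  for (it in seq_len(iterations)) {
    avg <- as.matrix(W %*% v) / deg
    v <- (1 - lambda) * v + lambda * avg
  }
  v
}

#' Gyral crown vertices
#'
#' Identifies gyral crowns as the pial vertices lying within `eps` of a
#' heavily smoothed outer envelope of the pial surface. The envelope is
#' obtained by uniform Laplacian smoothing of the coordinates
#' (`iterations` passes), then uniformly rescaled about its area-weighted
#' centroid so that the original surface lies inside it; crown membership
#' uses exact point-to-triangle distance to the envelope.
#'
#' @param pial pial `fcd_mesh`.
#' @param eps crown distance tolerance in mm.
#' @param iterations smoothing passes for the envelope.
#' @return integer vector of crown vertex indices.
#' @export
crown_vertices <- function(pial, eps = 0.5, iterations = 200) {
  stopifnot(inherits(pial, "fcd_mesh"))
  env <- .smooth_coordinates(pial, iterations)
  ctr <- colSums(env * pial$vertex_areas) / sum(pial$vertex_areas)
  ## scale the envelope outward until every pial vertex radius (about the
  ## centroid) is covered along its own direction
  re <- sqrt(rowSums(sweep(env, 2, ctr)^2))
  rp <- sqrt(rowSums(sweep(pial$vertices, 2, ctr)^2))
  s <- max(rp / pmax(re, 1e-9))
  env_scaled <- sweep(sweep(env, 2, ctr) * s, 2, ctr, `+`)
  d <- .cpp_point_surface_dist(pial$vertices, env_scaled, pial$faces)
  which(d <= eps)
}

#' Sulcal depth
#'
#' Geodesic distance from each pial vertex to the nearest gyral crown vertex
#' (multi-source Dijkstra on the pial edge graph); exactly 0 on the crown
#' set. On a flat mesh every vertex is a crown, so depth is 0 everywhere.
#'
#' @param pial pial `fcd_mesh`.
#' @param crowns optional integer vector of crown vertices; computed with
#'   [crown_vertices()] when omitted.
#' @param ... passed to [crown_vertices()].
#' @return an `fcd_scalar_map` in mm.
#' @export
sulcal_depth <- function(pial, crowns = NULL, ...) {
  if (is.null(crowns)) crowns <- crown_vertices(pial, ...)
  if (length(crowns) == 0L)
    stop("no crown vertices found; increase `eps` or check the surface")
  scalar_map(.geodesic_multisource(pial, crowns), "sulcal_depth", "mm")
}
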