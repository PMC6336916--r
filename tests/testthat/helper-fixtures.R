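# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

sphere_mesh <- function(radius = 50, subdivisions = 3) {
  ico <- icosphere(subdivisions)
  triangle_mesh(ico$vertices * radius, ico$faces)
}

plane_mesh <- function(nx = 15, ny = 15, spacing = 1) {
  g <- grid_mesh(nx, ny, spacing)
  triangle_mesh(g$vertices, g$faces)
}

interior_vertices <- function(mesh) which(!mesh$boundary)

# planar white/pial pair: horizontal grids at z = z_white and z = z_pial
planar_pair <- function(nx = 12, ny = 12, spacing = 2, z_white = 0, z_pial = 3) {
  g <- grid_mesh(nx, ny, spacing)
  w <- g$vertices; w[, 3] <- z_white
  p <- g$vertices; p[, 3] <- z_pial
  surface_pair(triangle_mesh(w, g$faces), triangle_mesh(p, g$faces))
}

# volume with value = f(x, y, z) on a centered integer grid
fn_volume <- function(f, half = 20, spacing = 1) {
  co <- seq(-half, half, by = spacing)
  arr <- array(0, c(length(co), length(co), length(co)))
  for (k in seq_along(co)) {
    xy <- expand.grid(x = co, y = co)
    arr[, , k] <- matrix(f(xy$x, xy$y, co[k]), length(co), length(co))
  }
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -half
  scalar_volume(arr, aff)
}

uniform_volume <- function(value = 100, half = 20)
  fn_volume(function(x, y, z) rep(value, length(x)), half)

ramp_volume <- function(half = 20)
  fn_volume(function(x, y, z) z, half)

# sharp two-compartment phantom: WM below z = 0 (voxel centers z <= -1),
# GM at z >= 0
two_compartment_volume <- function(gm = 80, wm = 120, half = 20)
  fn_volume(function(x, y, z) ifelse(z >= 0, gm, wm), half)

# igraph-based shortest-path oracle over the mesh edge graph
igraph_distances <- function(mesh, from) {
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  d <- igraph::distances(g, v = from, weights = mesh$edge_lengths)
  d[1, ]
}

tiny_spec <- function(...) {
  cohort_spec(n_patients = 2, n_controls = 2, subdivisions = 3,
              radius_mm = 30, ...)
}
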