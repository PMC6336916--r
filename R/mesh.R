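#' Triangle mesh for cortical surfaces
#'
#' Builds a validated triangle mesh from vertex coordinates (RAS millimetres)
#' and 1-based face indices, precomputing the per-vertex quantities the rest
#' of the pipeline relies on: neighbor lists, one-ring ("barycentric") vertex
#' areas, and outward unit normals derived from counterclockwise face winding.
#'
#' Validation enforces the mesh contract: all face indices must be in range,
#' every vertex must be referenced by at least one face, each edge may be
#' shared by at most two faces (2-manifold surface, boundary edges allowed),
#' and every vertex area must be strictly positive.
#'
#' @param vertices numeric N x 3 matrix of coordinates in mm.
#' @param faces integer M x 3 matrix of 1-based vertex indices,
#'   counterclockwise when viewed from outside.
#' @return an object of class `fcd_mesh` with components `vertices`, `faces`,
#'   `neighbors` (list of integer vectors), `vertex_areas`, `vertex_normals`,
#'   `edges` (E x 2, each undirected edge once), `edge_lengths`, and
#'   `boundary` (logical, vertices on a boundary edge).
#' @examples
#' ico <- icosphere(1)
#' m <- triangle_mesh(ico$vertices * 50, ico$faces)
#' abs(mesh_area(m) - 4 * pi * 50^2) / (4 * pi * 50^2) < 0.1
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("vertex coordinates must be finite")
  n <- nrow(vertices)
  if (anyNA(faces) || any(faces < 1L) || any(faces > n))
    stop("face indices out of range [1, ", n, "]")
  used <- tabulate(faces, nbins = n)
  if (any(used == 0L))
    stop(sum(used == 0L), " vertices are not referenced by any face")

  ## undirected edge table; manifold check
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  eu <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- (eu[, 1L] - 1) * n + eu[, 2L]
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than 2 faces")
  first <- !duplicated(key)
  edges <- eu[first, , drop = FALSE]
  ekey <- key[first]
  eshared <- as.integer(cnt[match(ekey, as.numeric(names(cnt)))])
  boundary_edge <- eshared == 1L
  boundary <- rep(FALSE, n)
  boundary[edges[boundary_edge, ]] <- TRUE

  geom <- .face_geometry(vertices, faces)
  if (any(geom$face_area <= 1e-12))
    warning("mesh contains ", sum(geom$face_area <= 1e-12),
            " degenerate (zero-area) faces")
  varea <- .accumulate(as.vector(faces), rep(geom$face_area / 3, 3L), n)
  if (any(varea <= 0))
    stop("per-vertex areas must be strictly positive")

  ## area-weighted vertex normals from CCW face normals
  nrm <- matrix(0, n, 3L)
  for (j in 1:3) {
    fi <- faces[, j]
    for (k in 1:3)
      nrm[, k] <- nrm[, k] + .accumulate(fi, geom$face_normal[, k] * geom$face_area, n)
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len

  nb <- .neighbor_list(edges, n)
  elen <- sqrt(rowSums((vertices[edges[, 1L], , drop = FALSE] -
                        vertices[edges[, 2L], , drop = FALSE])^2))

  structure(list(
    vertices = vertices, faces = faces, neighbors = nb,
    vertex_areas = varea, vertex_normals = nrm,
    edges = edges, edge_lengths = elen, boundary = boundary
  ), class = "fcd_mesh")
}

## per-face area and unit normal (CCW winding => outward)
.face_geometry <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  fn <- cr / ifelse(nrm2 == 0, 1, nrm2)
  list(face_area = nrm2 / 2, face_normal = fn)
}

.accumulate <- function(index, values, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

.neighbor_list <- function(edges, n) {
  i <- c(edges[, 1L], edges[, 2L])
  j <- c(edges[, 2L], edges[, 1L])
  ord <- order(i, j)
  split(j[ord], factor(i[ord], levels = seq_len(n)))
}

## CSR edge graph used by the compiled geodesic routines (0-based)
.mesh_csr <- function(mesh) {
  n <- nrow(mesh$vertices)
  i <- c(mesh$edges[, 1L], mesh$edges[, 2L])
  j <- c(mesh$edges[, 2L], mesh$edges[, 1L])
  w <- c(mesh$edge_lengths, mesh$edge_lengths)
  ord <- order(i)
  deg <- tabulate(i, nbins = n)
  list(off = as.integer(c(0L, cumsum(deg))),
       adj = as.integer(j[ord] - 1L), w = as.double(w[ord]))
}

#' @export
print.fcd_mesh <- function(x, ...) {
  cat("Triangle mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat("  total area:", format(sum(x$vertex_areas), digits = 6), "mm^2",
      if (any(x$boundary)) sprintf("(%d boundary vertices)", sum(x$boundary))
      else "(closed surface)", "\n")
  invisible(x)
}

#' Total mesh surface area
#'
#' Sum of the per-vertex areas; by construction equal to the sum of all
#' triangle areas.
#' @param mesh an `fcd_mesh`.
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh$vertex_areas)

#' White/pial cortical surface pair
#'
#' Couples the inner (GM/WM) and outer (pial) surfaces of one hemisphere.
#' The two meshes must have identical vertex counts and identical face
#' arrays: vertex i on the white surface corresponds to vertex i on the pial
#' surface.
#'
#' @param white,pial `fcd_mesh` objects with 1:1 vertex correspondence.
#' @return an object of class `fcd_surface_pair`.
#' @export
surface_pair <- function(white, pial) {
  stopifnot(inherits(white, "fcd_mesh"), inherits(pial, "fcd_mesh"))
  if (nrow(white$vertices) != nrow(pial$vertices))
    stop("white and pial surfaces must share the vertex count")
  if (!identical(white$faces, pial$faces))
    stop("white and pial surfaces must share the face array")
  structure(list(white = white, pial = pial, n = nrow(white$vertices)),
            class = "fcd_surface_pair")
}

#' @export
print.fcd_surface_pair <- function(x, ...) {
  cat("Cortical surface pair:", x$n, "shared vertices\n")
  invisible(x)
}

#' Per-vertex scalar map
#'
#' A length-N numeric vector attached to a surface, carrying a feature name
#' and units. `NA` marks invalid (masked) vertices, e.g. the medial wall or
#' out-of-volume samples; all statistics in the package skip masked vertices.
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param name feature name.
#' @param units unit string ("mm", "ratio", ...).
#' @return a classed numeric vector (`fcd_scalar_map`).
#' @export
scalar_map <- function(values, name = "map", units = "") {
  structure(as.double(values), name = name, units = units,
            class = "fcd_scalar_map")
}

#' @export
print.fcd_scalar_map <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("Scalar map '%s' [%s]: %d vertices (%d masked)\n",
              attr(x, "name"), attr(x, "units"), length(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Vertex label (lesion, resection, region of interest)
#'
#' A set of unique 1-based vertex indices with a name.
#' @param vertices integer vector of vertex indices.
#' @param name label name, e.g. "lesion" or "resection".
#' @param n_vertices optional mesh vertex count for range validation.
#' @return object of class `fcd_label`.
#' @export
vertex_label <- function(vertices, name = "label", n_vertices = NULL) {
  vertices <- sort(unique(as.integer(vertices)))
  if (length(vertices) && vertices[1L] < 1L)
    stop("label vertex indices must be >= 1")
  if (!is.null(n_vertices) && length(vertices) && max(vertices) > n_vertices)
    stop("label references vertex ", max(vertices),
         " but the mesh has only ", n_vertices, " vertices")
  structure(list(vertices = vertices, name = name), class = "fcd_label")
}

#' @export
print.fcd_label <- function(x, ...) {
  cat(sprintf("Vertex label '%s': %d vertices\n", x$name, length(x$vertices)))
  invisible(x)
}

#' Homotopic left-right vertex correspondence
#'
#' A bijection between left-hemisphere and right-hemisphere vertex indices at
#' mirror-corresponding (homotopic) cortical locations, as produced by
#' symmetric interhemispheric registration. Applying the map twice is the
#' identity.
#'
#' @param left_to_right integer vector: element i is the right-hemisphere
#'   vertex homotopic to left vertex i (`NA` for vertices with no
#'   correspondence, e.g. the medial wall).
#' @return object of class `fcd_homotopic`.
#' @export
homotopic_correspondence <- function(left_to_right) {
  left_to_right <- as.integer(left_to_right)
  ok <- !is.na(left_to_right)
  if (anyDuplicated(left_to_right[ok]))
    stop("homotopic correspondence must be a bijection")
  structure(list(left_to_right = left_to_right), class = "fcd_homotopic")
}
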