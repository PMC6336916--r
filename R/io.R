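.guess_format <- function(path) {
  if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "freesurfer"
}

#' Read and write cortical surface meshes
#'
#' Supports the FreeSurfer binary triangle-surface format and GIFTI surface
#' files (`.surf.gii`). Round-tripping a mesh reproduces coordinates to
#' float32 precision and faces exactly. The format is inferred from the file
#' extension unless given.
#'
#' @param path file path.
#' @param format `"auto"`, `"freesurfer"` or `"gifti"`.
#' @param mesh an `fcd_mesh` to write.
#' @return `read_surface()` returns an `fcd_mesh`.
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop("no such surface file: ", path)
  switch(format,
         freesurfer = .read_surface_fs(path),
         gifti = .read_surface_gifti(path))
}

#' @rdname read_surface
#' @export
write_surface <- function(mesh, path, format = c("auto", "freesurfer", "gifti")) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  switch(format,
         freesurfer = .write_surface_fs(mesh, path),
         gifti = .write_surface_gifti(mesh, path))
}

#' Read and write per-vertex scalar maps
#'
#' Supports the FreeSurfer "curv" binary format and GIFTI functional files
#' (`.func.gii`, `.shape.gii`). When `n_vertices` is supplied the vertex
#' count on disk must match it exactly; a mismatch is an error, never a
#' silent truncation.
#'
#' @param path file path.
#' @param format `"auto"`, `"curv"` or `"gifti"`.
#' @param n_vertices expected vertex count (optional consistency check).
#' @param map numeric vector or `fcd_scalar_map` to write.
#' @param name,units metadata attached to the returned map.
#' @return `read_scalar_map()` returns an `fcd_scalar_map`.
#' @export
read_scalar_map <- function(path, format = c("auto", "curv", "gifti"),
                            n_vertices = NULL, name = NULL, units = "") {
  format <- match.arg(format)
  if (format == "auto") format <- if (.guess_format(path) == "gifti") "gifti" else "curv"
  if (!file.exists(path)) stop("no such scalar map file: ", path)
  vals <- switch(format, curv = .read_curv_fs(path), gifti = .read_map_gifti(path))
  if (!is.null(n_vertices) && length(vals) != n_vertices)
    stop("scalar map has ", length(vals), " values but the mesh has ",
         n_vertices, " vertices: ", path)
  scalar_map(vals, name = if (is.null(name)) basename(path) else name,
             units = units)
}

#' @rdname read_scalar_map
#' @export
write_scalar_map <- function(map, path, format = c("auto", "curv", "gifti"),
                             n_vertices = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- if (.guess_format(path) == "gifti") "gifti" else "curv"
  vals <- as.double(map)
  if (!is.null(n_vertices) && length(vals) != n_vertices)
    stop("scalar map has ", length(vals), " values but the mesh has ",
         n_vertices, " vertices")
  switch(format,
         curv = .write_curv_fs(vals, path),
         gifti = .write_map_gifti(vals, path))
}

#' Read and write vertex labels
#'
#' Supports FreeSurfer ASCII `.label` files and GIFTI label arrays
#' (`.label.gii`). Labels round-trip exactly. Indices are 1-based in R and
#' converted to the formats' 0-based convention on disk.
#'
#' @param path file path.
#' @param format `"auto"`, `"freesurfer"` or `"gifti"`.
#' @param n_vertices mesh vertex count; required for GIFTI writing and used
#'   as a consistency check when reading.
#' @param label an `fcd_label` or integer vector of vertex indices.
#' @param name label name for the returned object.
#' @param coords optional N x 3 coordinates written into FreeSurfer labels.
#' @return `read_label()` returns an `fcd_label`.
#' @export
read_label <- function(path, format = c("auto", "freesurfer", "gifti"),
                       n_vertices = NULL, name = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop("no such label file: ", path)
  idx <- switch(format,
                freesurfer = .read_label_fs(path),
                gifti = .read_label_gifti(path))
  if (!is.null(n_vertices) && length(idx) && max(idx) > n_vertices)
    stop("label references vertex ", max(idx), " beyond the mesh's ",
         n_vertices, " vertices: ", path)
  vertex_label(idx, name = if (is.null(name)) basename(path) else name,
               n_vertices = n_vertices)
}

#' @rdname read_label
#' @export
write_label <- function(label, path, format = c("auto", "freesurfer", "gifti"),
                        n_vertices = NULL, coords = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  idx <- if (inherits(label, "fcd_label")) label$vertices else
    sort(unique(as.integer(label)))
  if (!is.null(n_vertices) && length(idx) && max(idx) > n_vertices)
    stop("label references vertex ", max(idx), " beyond the mesh's ",
         n_vertices, " vertices")
  switch(format,
         freesurfer = .write_label_fs(idx, path, coords = coords),
         gifti = {
           if (is.null(n_vertices))
             stop("n_vertices is required to write a GIFTI label")
           .write_label_gifti(idx, n_vertices, path)
         })
}

#' Scalar volume with RAS affine
#'
#' A 3-D intensity array plus the 4x4 affine mapping 0-based voxel indices
#' to RAS world coordinates in mm (the NIfTI convention).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world affine; must be invertible.
#' @return object of class `fcd_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4)) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine), class = "fcd_volume")
}

#' @export
print.fcd_volume <- function(x, ...) {
  cat("Scalar volume:", paste(dim(x$data), collapse = " x "),
      "voxels; origin", paste(round(x$affine[1:3, 4], 2), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write NIfTI scalar volumes
#'
#' Thin wrappers over the RNifti package; the affine returned by
#' `read_volume()` maps 0-based voxel indices to RAS mm.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param volume an `fcd_volume` to write.
#' @return `read_volume()` returns an `fcd_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  scalar_volume(as.array(img), matrix(as.numeric(aff), 4L, 4L))
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "fcd_volume"))
  img <- RNifti::asNifti(volume$data, datatype = "float")
  img <- RNifti::`qform<-`(img, structure(volume$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
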