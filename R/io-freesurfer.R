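## FreeSurfer binary surface / curv / label readers and writers.
## All on-disk vertex indices are 0-based (converted to 1-based in R);
## binary formats are big-endian.

.fs_read_magic <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) stop("truncated FreeSurfer file")
  sum(b * c(65536, 256, 1))
}

.fs_write_magic <- function(con, magic) {
  writeBin(as.integer(c(magic %/% 65536, (magic %/% 256) %% 256, magic %% 256)),
           con, size = 1L)
}

.fs_read_line <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L || b == as.raw(10L)) break
    out <- c(out, b)
  }
  rawToChar(out)
}

.read_surface_fs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .fs_read_magic(con)
  if (magic != 16777214)  # 0xFFFFFE, triangle file
    stop("not a FreeSurfer triangle surface (bad magic): ", path)
  .fs_read_line(con)  # creation comment
  .fs_read_line(con)  # empty line terminating the header
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (is.na(nv) || is.na(nf) || nv <= 0L || nf <= 0L)
    stop("malformed FreeSurfer surface header: ", path)
  v <- readBin(con, "double", nv * 3L, size = 4L, endian = "big")
  f <- readBin(con, "integer", nf * 3L, size = 4L, endian = "big")
  if (length(v) < nv * 3L || length(f) < nf * 3L)
    stop("truncated FreeSurfer surface data: ", path)
  triangle_mesh(matrix(v, ncol = 3L, byrow = TRUE),
                matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

.write_surface_fs <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  .fs_write_magic(con, 16777214)
  writeBin(charToRaw("created by fcdsurf\n\n"), con)
  writeBin(as.integer(c(nrow(mesh$vertices), nrow(mesh$faces))), con,
           size = 4L, endian = "big")
  writeBin(as.double(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

.read_curv_fs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .fs_read_magic(con)
  if (magic != 16777215)  # 0xFFFFFF, "new" curv format
    stop("not a FreeSurfer curv file (bad magic): ", path)
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  readBin(con, "integer", 1L, size = 4L, endian = "big")  # face count, unused
  vpv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (is.na(nv) || nv <= 0L || vpv != 1L)
    stop("malformed FreeSurfer curv header: ", path)
  vals <- readBin(con, "double", nv, size = 4L, endian = "big")
  if (length(vals) < nv) stop("truncated FreeSurfer curv data: ", path)
  vals
}

.write_curv_fs <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  .fs_write_magic(con, 16777215)
  writeBin(as.integer(c(length(values), 0L, 1L)), con, size = 4L, endian = "big")
  writeBin(as.double(values), con, size = 4L, endian = "big")
  invisible(path)
}

.read_label_fs <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#"))
    stop("not a FreeSurfer label file: ", path)
  nv <- as.integer(lines[2L])
  if (is.na(nv) || nv < 0L || length(lines) < 2L + nv)
    stop("malformed FreeSurfer label file: ", path)
  if (nv == 0L) return(integer(0))
  tab <- utils::read.table(text = lines[3:(2L + nv)])
  as.integer(tab[[1L]]) + 1L
}

.write_label_fs <- function(vertices, path, coords = NULL) {
  vertices <- sort(unique(as.integer(vertices)))
  if (is.null(coords)) coords <- matrix(0, length(vertices), 3L)
  lines <- c(
    "#!ascii label, written by fcdsurf",
    as.character(length(vertices)),
    sprintf("%d  %.3f  %.3f  %.3f 0.0000000000",
            vertices - 1L, coords[, 1L], coords[, 2L], coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}
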