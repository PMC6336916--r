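## Minimal GIFTI (.gii) reader/writer covering the dialects the pipeline
## needs: surface (POINTSET + TRIANGLE), per-vertex functional/shape data,
## and integer label arrays. Data are written Base64-encoded little-endian;
## Base64Binary and GZipBase64Binary encodings are read.

.gifti_dtype <- c(NIFTI_TYPE_FLOAT32 = "float32", NIFTI_TYPE_INT32 = "int32",
                  NIFTI_TYPE_FLOAT64 = "float64", NIFTI_TYPE_UINT8 = "uint8")

.gifti_decode_data <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  endian <- xml2::xml_attr(node, "Endian")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- vapply(paste0("Dim", 0:5), function(a)
    suppressWarnings(as.integer(xml2::xml_attr(node, a))), integer(1L))
  dims <- dims[!is.na(dims)]
  nelem <- prod(dims)
  txt <- gsub("\\s", "", xml2::xml_text(xml2::xml_find_first(node, ".//d1:Data",
              c(d1 = "http://www.nitrc.org/frs/download.php/115/gifti.xsd"))))
  if (is.na(txt) || txt == "") {
    txt <- gsub("\\s", "", xml2::xml_text(xml2::xml_find_first(node, ".//Data")))
  }
  raw <- jsonlite::base64_dec(txt)
  if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, type = "gzip")
  else if (!identical(enc, "Base64Binary"))
    stop("unsupported GIFTI encoding: ", enc)
  e <- if (identical(endian, "BigEndian")) "big" else "little"
  vals <- switch(.gifti_dtype[[dtype]],
    float32 = readBin(raw, "double", nelem, size = 4L, endian = e),
    float64 = readBin(raw, "double", nelem, size = 8L, endian = e),
    int32 = readBin(raw, "integer", nelem, size = 4L, endian = e),
    uint8 = readBin(raw, "integer", nelem, size = 1L, signed = FALSE, endian = e),
    stop("unsupported GIFTI data type: ", dtype))
  if (length(vals) != nelem) stop("truncated GIFTI data array")
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  if (length(dims) == 2L) {
    m <- if (identical(order, "ColumnMajorOrder")) matrix(vals, nrow = dims[1L])
         else matrix(vals, ncol = dims[2L], byrow = TRUE)
    m
  } else vals
}

.gifti_read_arrays <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GIFTI file: ", path))
  if (xml2::xml_name(doc) != "GIFTI") stop("not a GIFTI file: ", path)
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(nodes) == 0L)
    nodes <- xml2::xml_find_all(doc, ".//d1:DataArray",
        c(d1 = "http://www.nitrc.org/frs/download.php/115/gifti.xsd"))
  lapply(nodes, function(nd) {
    list(intent = xml2::xml_attr(nd, "Intent"), data = .gifti_decode_data(nd))
  })
}

.gifti_encode <- function(x, dtype) {
  raw <- switch(dtype,
    NIFTI_TYPE_FLOAT32 = writeBin(as.double(x), raw(), size = 4L, endian = "little"),
    NIFTI_TYPE_INT32 = writeBin(as.integer(x), raw(), size = 4L, endian = "little"))
  jsonlite::base64_enc(raw)
}

.gifti_array_xml <- function(values, intent, dtype) {
  if (is.matrix(values)) {
    dims <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                    nrow(values), ncol(values))
    flat <- as.vector(t(values))
  } else {
    dims <- sprintf('Dimensionality="1" Dim0="%d"', length(values))
    flat <- values
  }
  paste0(
    '<DataArray Intent="', intent, '" DataType="', dtype,
    '" ArrayIndexingOrder="RowMajorOrder" ', dims,
    ' Encoding="Base64Binary" Endian="LittleEndian" ExternalFileName=""',
    ' ExternalFileOffset="">\n<Data>', .gifti_encode(flat, dtype),
    '</Data>\n</DataArray>')
}

.gifti_write <- function(arrays, path) {
  body <- vapply(arrays, function(a)
    .gifti_array_xml(a$data, a$intent, a$dtype), character(1L))
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" Version="1.0" ',
    'NumberOfDataArrays="', length(arrays), '">\n',
    paste(body, collapse = "\n"), '\n</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

.read_surface_gifti <- function(path) {
  arrays <- .gifti_read_arrays(path)
  intents <- vapply(arrays, `[[`, character(1L), "intent")
  iv <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(iv) != 1L || length(it) != 1L)
    stop("GIFTI surface must contain one POINTSET and one TRIANGLE array: ", path)
  triangle_mesh(arrays[[iv]]$data, arrays[[it]]$data + 1L)
}

.write_surface_gifti <- function(mesh, path) {
  .gifti_write(list(
    list(data = mesh$vertices, intent = "NIFTI_INTENT_POINTSET",
         dtype = "NIFTI_TYPE_FLOAT32"),
    list(data = mesh$faces - 1L, intent = "NIFTI_INTENT_TRIANGLE",
         dtype = "NIFTI_TYPE_INT32")), path)
}

.read_map_gifti <- function(path) {
  arrays <- .gifti_read_arrays(path)
  if (length(arrays) < 1L) stop("GIFTI func file has no data array: ", path)
  as.double(arrays[[1L]]$data)
}

.write_map_gifti <- function(values, path) {
  .gifti_write(list(list(data = as.double(values), intent = "NIFTI_INTENT_NONE",
                         dtype = "NIFTI_TYPE_FLOAT32")), path)
}

.read_label_gifti <- function(path) {
  arrays <- .gifti_read_arrays(path)
  keys <- as.integer(arrays[[1L]]$data)
  which(keys != 0L)
}

.write_label_gifti <- function(vertices, n_vertices, path) {
  keys <- integer(n_vertices)
  keys[vertices] <- 1L
  body <- paste0(
    '<LabelTable>\n',
    '<Label Key="0" Red="0" Green="0" Blue="0" Alpha="0"><![CDATA[???]]></Label>\n',
    '<Label Key="1" Red="1" Green="0" Blue="0" Alpha="1"><![CDATA[label]]></Label>\n',
    '</LabelTable>')
  arr <- .gifti_array_xml(keys, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32")
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n', body, "\n", arr,
    '\n</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}
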