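#' @include flatmesh.R
NULL

# Minimal GIFTI (.gii) support: surface geometry (.surf.gii: POINTSET +
# TRIANGLE arrays) and label files (.label.gii: LABEL array + LabelTable).
# Encodings handled: ASCII, Base64Binary, GZipBase64Binary. Writing uses
# ASCII, which round trips int32 exactly and doubles via 17 digits.

.readGiftiArrays <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, "//DataArray")
  lapply(arrays, function(a) {
    intent <- xml2::xml_attr(a, "Intent")
    dtype <- xml2::xml_attr(a, "DataType")
    ndim <- as.integer(xml2::xml_attr(a, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(d)
      as.integer(xml2::xml_attr(a, paste0("Dim", d))), integer(1))
    order <- xml2::xml_attr(a, "ArrayIndexingOrder")
    dataNode <- xml2::xml_find_first(a, ".//Data")
    enc <- xml2::xml_attr(a, "Encoding")
    endian <- xml2::xml_attr(a, "Endian")
    endian <- if (!is.na(endian) && grepl("Big", endian)) "big" else "little"
    txt <- xml2::xml_text(dataNode)
    what <- if (grepl("FLOAT", dtype)) "numeric" else "integer"
    n <- prod(dims)
    if (is.na(enc) || enc == "ASCII") {
      vals <- scan(text = txt, what = double(), quiet = TRUE)
      if (what == "integer") vals <- as.integer(round(vals))
    } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      vals <- readBin(raw, what, n = n, size = 4L, endian = endian)
    } else {
      cgridStop(sprintf("unsupported GIFTI encoding '%s'", enc),
                "cgrid_format_error")
    }
    mat <- if (length(dims) == 2L) {
      if (!is.na(order) && order == "ColumnMajorOrder")
        matrix(vals, nrow = dims[1], ncol = dims[2])
      else
        matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    } else vals
    list(intent = intent, data = mat)
  })
}

.readGiftiSurface <- function(path) {
  arrays <- .readGiftiArrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(ip) || !length(it))
    cgridStop(sprintf("'%s' lacks POINTSET/TRIANGLE arrays", path),
              "cgrid_format_error")
  xyz <- arrays[[ip[1]]]$data
  faces <- arrays[[it[1]]]$data
  if (nrow(faces) > 0L) {
    if (any(faces < 0L) || any(faces >= nrow(xyz)))
      cgridStop("GIFTI surface: face references a nonexistent vertex",
                "cgrid_index_error")
    faces <- faces + 1L
  }
  list(xyz = xyz, faces = faces)
}

.readGiftiLabels <- function(path) {
  doc <- xml2::read_xml(path)
  labNodes <- xml2::xml_find_all(doc, "//LabelTable/Label")
  keys <- as.integer(xml2::xml_attr(labNodes, "Key"))
  names <- xml2::xml_text(labNodes)
  arrays <- .readGiftiArrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  il <- which(intents == "NIFTI_INTENT_LABEL")
  if (!length(il))
    cgridStop(sprintf("'%s' lacks a LABEL array", path), "cgrid_format_error")
  codes <- as.integer(arrays[[il[1]]]$data)
  list(codes = codes, table = stats::setNames(names, as.character(keys)))
}

.giiEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.writeGiftiSurface <- function(xyz, faces, path) {
  fmtRow <- function(m, fmt) paste(apply(m, 1L, function(r)
    paste(sprintf(fmt, r), collapse = " ")), collapse = "\n")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="2">'),
    sprintf('<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT32" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="%d" Dim1="3" Encoding="ASCII" Endian="LittleEndian">',
            nrow(xyz)),
    "<Data>", fmtRow(xyz, "%.17g"), "</Data>", "</DataArray>",
    sprintf('<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="%d" Dim1="3" Encoding="ASCII" Endian="LittleEndian">',
            nrow(faces)),
    "<Data>", if (nrow(faces)) fmtRow(faces - 1L, "%d") else "", "</Data>",
    "</DataArray>", "</GIFTI>")
  writeLines(lines, path)
  invisible(path)
}

.writeGiftiLabels <- function(labels, path) {
  uniq <- sort(unique(labels))
  keys <- seq_along(uniq)
  codes <- keys[match(labels, uniq)]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">',
    "<LabelTable>",
    sprintf('<Label Key="%d" Red="0.5" Green="0.5" Blue="0.5" Alpha="1">%s</Label>',
            keys, .giiEscape(uniq)),
    "</LabelTable>",
    sprintf('<DataArray Intent="NIFTI_INTENT_LABEL" DataType="NIFTI_TYPE_INT32" ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="%d" Encoding="ASCII" Endian="LittleEndian">',
            length(labels)),
    "<Data>", paste(codes, collapse = " "), "</Data>",
    "</DataArray>", "</GIFTI>")
  writeLines(lines, path)
  invisible(path)
}
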