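#' @include flatmesh.R
NULL

# FreeSurfer binary formats (big-endian): triangle surface files and .annot
# annotation files. Only the parts needed for flat maps are implemented.

.FS_TRIANGLE_MAGIC <- c(255L, 255L, 254L)

.readFsSurface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- as.integer(readBin(con, "raw", 3L))
  if (!identical(magic, .FS_TRIANGLE_MAGIC))
    cgridStop(sprintf("'%s' is not a FreeSurfer triangle surface", path),
              "cgrid_format_error")
  # comment string terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L)
      cgridStop("unexpected end of FreeSurfer surface header", "cgrid_format_error")
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  xyz <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "big")
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    faces <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
    faces <- matrix(faces, ncol = 3L, byrow = TRUE)
    if (any(faces < 0L) || any(faces >= nv))
      cgridStop("FreeSurfer surface: face references a nonexistent vertex",
                "cgrid_index_error")
    faces <- faces + 1L
  }
  list(xyz = xyz, faces = faces)
}

.writeFsSurface <- function(xyz, faces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(.FS_TRIANGLE_MAGIC), con)
  writeChar("created by cgrid\n\n", con, eos = NULL)
  writeBin(as.integer(nrow(xyz)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(faces)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(xyz)), con, size = 4L, endian = "big")
  if (nrow(faces) > 0L)
    writeBin(as.integer(t(faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

.readFsAnnot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  data <- readBin(con, "integer", 2L * nv, size = 4L, endian = "big")
  data <- matrix(data, ncol = 2L, byrow = TRUE)  # vertex index, label code
  codes <- integer(nv)
  codes[data[, 1] + 1L] <- data[, 2]
  tag <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  table <- NULL
  if (length(tag) == 1L && tag == 1L) {
    version <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (version >= 0L)
      cgridStop("old-style .annot colortables are not supported",
                "cgrid_format_error")
    readBin(con, "integer", 1L, size = 4L, endian = "big")  # max structure id
    flen <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    readBin(con, "raw", flen)                               # source filename
    nEntries <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    names <- character(nEntries); rgbcodes <- integer(nEntries)
    for (i in seq_len(nEntries)) {
      readBin(con, "integer", 1L, size = 4L, endian = "big")  # structure id
      len <- readBin(con, "integer", 1L, size = 4L, endian = "big")
      nm <- readBin(con, "raw", len)
      names[i] <- rawToChar(nm[nm != as.raw(0)])
      rgb <- readBin(con, "integer", 4L, size = 4L, endian = "big")
      rgbcodes[i] <- rgb[1] + rgb[2] * 256L + rgb[3] * 65536L
    }
    table <- stats::setNames(names, as.character(rgbcodes))
  }
  list(codes = codes, table = table)
}

.writeFsAnnot <- function(labels, path) {
  uniq <- sort(unique(labels))
  # deterministic distinct colors -> codes
  r <- (seq_along(uniq) * 37L) %% 256L
  g <- (seq_along(uniq) * 101L) %% 256L
  b <- seq_along(uniq) %% 256L
  codes <- r + g * 256L + b * 65536L
  vcode <- codes[match(labels, uniq)]
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- length(labels)
  writeBin(nv, con, size = 4L, endian = "big")
  writeBin(as.integer(rbind(seq_len(nv) - 1L, vcode)), con,
           size = 4L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")   # colortable tag
  writeBin(-2L, con, size = 4L, endian = "big")  # new-format version
  writeBin(length(uniq), con, size = 4L, endian = "big")
  fname <- charToRaw("cgrid.ctab")
  writeBin(length(fname), con, size = 4L, endian = "big")
  writeBin(fname, con)
  writeBin(length(uniq), con, size = 4L, endian = "big")
  for (i in seq_along(uniq)) {
    writeBin(i - 1L, con, size = 4L, endian = "big")
    nm <- charToRaw(uniq[i])
    writeBin(length(nm), con, size = 4L, endian = "big")
    writeBin(nm, con)
    writeBin(c(r[i], g[i], b[i], 0L), con, size = 4L, endian = "big")
  }
  invisible(path)
}
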