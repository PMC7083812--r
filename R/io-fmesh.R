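#' @include flatmesh.R
NULL

# Plain-text mesh dialect "fmesh":
#   fmesh v1
#   H <hemisphere>          (optional)
#   V <count>
#   <x> <y> <label>         (V lines; label may contain single spaces)
#   F <count>
#   <i> <j> <k>             (F lines; 0-based vertex indices)
# Coordinates are written with 17 significant digits so that write -> read
# round trips doubles bit-exactly.

.readFmesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !identical(trimws(lines[1]), "fmesh v1"))
    cgridStop(sprintf("'%s' is not an fmesh v1 file", path), "cgrid_format_error")
  i <- 2L
  hemi <- "left"
  if (startsWith(lines[i], "H ")) {
    hemi <- trimws(sub("^H ", "", lines[i]))
    i <- i + 1L
  }
  if (!startsWith(lines[i], "V "))
    cgridStop("fmesh: expected 'V <count>' line", "cgrid_format_error")
  nv <- as.integer(sub("^V ", "", lines[i]))
  vlines <- lines[(i + 1L):(i + nv)]
  i <- i + nv + 1L
  m <- regmatches(vlines, regexec("^(\\S+)\\s+(\\S+)\\s+(.*)$", vlines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    cgridStop(sprintf("fmesh: malformed vertex line %d", which(bad)[1]),
              "cgrid_format_error")
  x <- as.numeric(vapply(m, `[[`, character(1), 2L))
  y <- as.numeric(vapply(m, `[[`, character(1), 3L))
  labels <- vapply(m, `[[`, character(1), 4L)
  if (anyNA(x) || anyNA(y))
    cgridStop("fmesh: non-numeric vertex coordinate", "cgrid_format_error")
  if (!startsWith(lines[i], "F "))
    cgridStop("fmesh: expected 'F <count>' line", "cgrid_format_error")
  nf <- as.integer(sub("^F ", "", lines[i]))
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    flines <- lines[(i + 1L):(i + nf)]
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), as.integer))
    if (ncol(faces) != 3L || anyNA(faces))
      cgridStop("fmesh: malformed face line", "cgrid_format_error")
    if (any(faces < 0L) || any(faces >= nv))
      cgridStop("fmesh: face references a nonexistent vertex",
                "cgrid_index_error")
    faces <- faces + 1L
  }
  FlatMesh(cbind(x, y), faces, labels, hemisphere = hemi)
}

.writeFmesh <- function(mesh, path) {
  v <- mesh@vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("fmesh v1", paste("H", mesh@hemisphere),
               paste("V", nrow(v))), con)
  writeLines(sprintf("%.17g %.17g %s", v[, 1], v[, 2], mesh@labels), con)
  writeLines(paste("F", nFaces(mesh)), con)
  if (nFaces(mesh) > 0L) {
    f <- mesh@faces - 1L
    writeLines(sprintf("%d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}
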