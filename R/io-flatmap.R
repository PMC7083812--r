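#' @include io-fmesh.R io-freesurfer.R io-gifti.R
NULL

# flat maps exported from 3D tools carry a z column that must be negligible;
# silently projecting a curved surface would corrupt distances
.dropZ <- function(xyz, path) {
  if (ncol(xyz) == 2L) return(xyz)
  extent <- max(diff(range(xyz[, 1])), diff(range(xyz[, 2])))
  if (max(abs(xyz[, 3])) > 1e-6 * extent)
    cgridStop(sprintf(
      "'%s' is not flat: |z| up to %.3g exceeds 1e-6 of the xy extent",
      path, max(abs(xyz[, 3]))), "cgrid_geometry_error")
  xyz[, 1:2, drop = FALSE]
}

.resolveLabels <- function(codes, table) {
  nm <- table[as.character(codes)]
  nm[is.na(nm)] <- "unknown"
  unname(nm)
}

.checkDialectTable <- function(table, dialect, path) {
  if (is.null(dialect)) return(invisible())
  missing <- setdiff(unname(dialect), table)
  if (length(missing))
    cgridStop(sprintf("label table of '%s' lacks dialect label(s): %s",
                      path, paste(missing, collapse = ", ")),
              "cgrid_label_error")
  invisible()
}

#' Read a labeled flat map
#'
#' Reads one of the three supported flat-map representations:
#' \describe{
#'   \item{fmesh}{the plain-text dialect (`*.fmesh`): header `fmesh v1`,
#'     vertex block `x y label`, face block of 0-based index triples.}
#'   \item{FreeSurfer}{a binary triangle surface plus a `.annot` annotation
#'     (pass the annotation as `labels`).}
#'   \item{GIFTI}{a `.surf.gii` geometry file plus a `.label.gii` label file
#'     (pass the label file as `labels`).}
#' }
#' Sources with a z coordinate are accepted only when `max |z|` is below
#' 1e-6 of the xy extent (flat maps exported from 3D tools sit numerically
#' on a plane); otherwise loading refuses rather than silently projecting.
#'
#' @param path path to the mesh file.
#' @param dialect optional [labelDialect()]; when given and the source carries
#'   a label table, every dialect label must be present in the table.
#' @param labels path to the annotation/label file (FreeSurfer and GIFTI).
#' @param hemisphere hemisphere tag for sources that do not record one.
#' @return a [FlatMesh-class].
#' @seealso [writeFlatmap()]
#' @export
loadFlatmap <- function(path, dialect = NULL, labels = NULL,
                        hemisphere = "left") {
  if (!file.exists(path))
    cgridStop(sprintf("file '%s' does not exist", path), "cgrid_file_error")
  if (grepl("\\.fmesh$", path) || grepl("\\.txt$", path)) {
    mesh <- .readFmesh(path)
    return(mesh)
  }
  if (grepl("\\.gii$", path)) {
    if (is.null(labels))
      cgridStop("GIFTI surfaces require a .label.gii via 'labels'",
                "cgrid_file_error")
    if (!file.exists(labels))
      cgridStop(sprintf("file '%s' does not exist", labels), "cgrid_file_error")
    surf <- .readGiftiSurface(path)
    lab <- .readGiftiLabels(labels)
  } else {
    if (is.null(labels))
      cgridStop("FreeSurfer surfaces require a .annot file via 'labels'",
                "cgrid_file_error")
    if (!file.exists(labels))
      cgridStop(sprintf("file '%s' does not exist", labels), "cgrid_file_error")
    surf <- .readFsSurface(path)
    lab <- .readFsAnnot(labels)
  }
  if (length(lab$codes) != nrow(surf$xyz))
    cgridStop("label file has a different vertex count than the surface",
              "cgrid_index_error")
  .checkDialectTable(lab$table, dialect, path)
  xy <- .dropZ(surf$xyz, path)
  FlatMesh(xy, surf$faces, .resolveLabels(lab$codes, lab$table),
           hemisphere = hemisphere)
}

#' Write a flat map
#'
#' @param mesh a [FlatMesh-class].
#' @param path output path. For `"freesurfer"` this is the surface file; for
#'   `"gifti"` the `.surf.gii` geometry file.
#' @param format `"fmesh"`, `"freesurfer"` or `"gifti"`.
#' @param labels path for the annotation/label file; defaults to
#'   `paste0(path, ".annot")` or the `.label.gii` sibling.
#' @return the main output path, invisibly.
#' @export
writeFlatmap <- function(mesh, path,
                         format = c("fmesh", "freesurfer", "gifti"),
                         labels = NULL) {
  format <- match.arg(format)
  if (format == "fmesh") return(.writeFmesh(mesh, path))
  xyz <- cbind(mesh@vertices, 0)
  if (format == "freesurfer") {
    if (is.null(labels)) labels <- paste0(path, ".annot")
    .writeFsSurface(xyz, mesh@faces, path)
    .writeFsAnnot(mesh@labels, labels)
  } else {
    if (is.null(labels)) labels <- sub("\\.surf\\.gii$", ".label.gii", path)
    if (identical(labels, path)) labels <- paste0(path, ".label.gii")
    .writeGiftiSurface(xyz, mesh@faces, path)
    .writeGiftiLabels(mesh@labels, labels)
  }
  invisible(path)
}
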