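#' @import methods
NULL

#' FlatMesh: a flattened, labeled cortical surface mesh
#'
#' A 2D face-vertex mesh produced by cortical flattening, with one atlas ROI
#' label per vertex. Coordinates are in the source's arbitrary units (a.u.);
#' no rescaling to millimetres is performed (1 a.u. approximates 1 mm for
#' typical flat maps).
#'
#' @slot vertices numeric matrix, one row per vertex, columns `x`, `y` (a.u.).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot labels character vector, one atlas ROI label per vertex.
#' @slot hemisphere `"left"` or `"right"`.
#' @slot metadata list of free-form metadata. Synthetic meshes store the
#'   ground-truth parametric coordinates here (see [makeSubjectFlatmap()]);
#'   the grid pipeline never reads them.
#'
#' @seealso [FlatMesh()], [loadFlatmap()], [vertexNeighbors()]
#' @export
setClass("FlatMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    labels = "character",
    hemisphere = "character",
    metadata = "list"
  )
)

setValidity("FlatMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  msgs <- character(0)
  if (!is.numeric(v) || ncol(v) != 2L)
    msgs <- c(msgs, "vertices must be a numeric matrix with 2 columns (x, y)")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L)
      msgs <- c(msgs, "faces must have 3 columns")
    else {
      if (any(f < 1L) || any(f > nrow(v)))
        msgs <- c(msgs, "face references a nonexistent vertex")
      dg <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
      if (any(dg))
        msgs <- c(msgs, sprintf("%d degenerate face(s) with repeated vertex indices", sum(dg)))
    }
  }
  if (length(object@labels) != nrow(v))
    msgs <- c(msgs, "labels must have exactly one entry per vertex")
  if (length(object@hemisphere) != 1L || !object@hemisphere %in% c("left", "right"))
    msgs <- c(msgs, "hemisphere must be \"left\" or \"right\"")
  if (length(msgs)) msgs else TRUE
})

#' Border: vertices of one atlas region adjacent to another
#'
#' The set of vertices carrying a given label that have at least one mesh
#' neighbor carrying one of a second set of labels. Stored unordered; ordering
#' along the dorsoventral axis happens inside polynomial fitting.
#'
#' @slot role one of `"central_sulcus"`, `"precentral_sulcus"`,
#'   `"postcentral_sulcus"`, `"dorsal"`, `"ventral"`, or `"custom"`.
#' @slot vertices integer vector of 1-based vertex indices.
#' @export
setClass("Border",
  representation(role = "character", vertices = "integer")
)

setValidity("Border", function(object) {
  if (length(object@role) != 1L) return("role must be a single string")
  if (length(object@vertices) == 0L) return("border vertex set is empty")
  TRUE
})

#' BorderSet: the five sensorimotor borders of one hemisphere
#'
#' @slot borders named list of five [Border-class] objects with names
#'   `central_sulcus`, `precentral_sulcus`, `postcentral_sulcus`,
#'   `dorsal`, `ventral`.
#' @slot dialect the named label dialect used for extraction
#'   (see [labelDialect()]).
#' @export
setClass("BorderSet",
  representation(borders = "list", dialect = "character")
)

.borderRoles <- c("central_sulcus", "precentral_sulcus", "postcentral_sulcus",
                  "dorsal", "ventral")

setValidity("BorderSet", function(object) {
  if (!identical(sort(names(object@borders)), sort(.borderRoles)))
    return("borders must contain exactly the five sensorimotor roles")
  if (!all(vapply(object@borders, is, logical(1), "Border")))
    return("all elements must be Border objects")
  TRUE
})

#' CgridDefinition: the tiled Cartesian grid imposed on a flat map
#'
#' Holds the M+1 truncated, equal-arc resampled vertical curves (ordered
#' precentral to postcentral, nodes ordered ventral to dorsal), the vertex to
#' tile assignment, and geometry metadata. Tile `(r, c)` in construction space
#' (row r counted from the ventral side, column c from the precentral side) is
#' the quadrilateral of nodes r and r+1 on curves c and c+1; its 1-based
#' row-major id is `(r-1)*M + c`.
#'
#' @slot nRows number of rows N (dorsoventral segments).
#' @slot nCols number of columns M (anteroposterior, must be even).
#' @slot curves list of M+1 matrices, each (N+1) x 2 (`x`, `y`).
#' @slot assignment integer vector, one entry per mesh vertex: row-major tile
#'   id, or `NA` for vertices enclosed by no tile.
#' @slot smxVertex logical vector flagging vertices labeled precentral or
#'   postcentral (the region of interest proper).
#' @slot yRange numeric `(y_min, y_max)` from the ventral/dorsal borders.
#' @slot xReversed `TRUE` when the precentral side lies at larger x on this
#'   flat map (mirrored hemisphere), i.e. curve order runs right-to-left.
#' @slot hemisphere hemisphere tag inherited from the mesh.
#' @slot curveLengths numeric vector of the M+1 truncated curve arc lengths.
#' @export
setClass("CgridDefinition",
  representation(
    nRows = "integer",
    nCols = "integer",
    curves = "list",
    assignment = "integer",
    smxVertex = "logical",
    yRange = "numeric",
    xReversed = "logical",
    hemisphere = "character",
    curveLengths = "numeric"
  )
)

setValidity("CgridDefinition", function(object) {
  N <- object@nRows; M <- object@nCols
  if (length(object@curves) != M + 1L)
    return(sprintf("expected %d curves, got %d", M + 1L, length(object@curves)))
  nn <- vapply(object@curves, nrow, integer(1))
  if (!all(nn == N + 1L))
    return(sprintf("every curve must have %d nodes", N + 1L))
  ok <- is.na(object@assignment) |
    (object@assignment >= 1L & object@assignment <= N * M)
  if (!all(ok)) return("assignment contains out-of-range tile ids")
  if (length(object@smxVertex) != length(object@assignment))
    return("smxVertex and assignment must have one entry per vertex")
  TRUE
})

#' CgridMap: a scalar field averaged into grid tiles
#'
#' An N x M matrix of tile values plus a validity mask. Values are stored in
#' display convention: row 1 is the dorsal edge, columns run left to right in
#' flat-map x order. [orientGrid()] flips the mirrored hemisphere so that the
#' precentral side is on the left regardless of hemisphere.
#'
#' @slot values numeric N x M matrix; invalid tiles are `NA`.
#' @slot mask logical N x M matrix; `TRUE` where the tile contains at least
#'   one region-of-interest vertex with a finite value.
#' @slot subject subject identifier.
#' @slot hemisphere `"left"` or `"right"`.
#' @slot task task name (e.g. `"feet"`).
#' @slot field name of the mapped vertex field.
#' @slot oriented `TRUE` after [orientGrid()] has applied the display
#'   convention.
#' @export
setClass("CgridMap",
  representation(
    values = "matrix",
    mask = "matrix",
    subject = "character",
    hemisphere = "character",
    task = "character",
    field = "character",
    oriented = "logical"
  )
)

setValidity("CgridMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (any(is.na(object@values[object@mask])))
    return("masked-valid tiles must carry finite values")
  if (!all(is.na(object@values[!object@mask])))
    return("invalid tiles must be NA")
  TRUE
})

#' RoiSlice: one half (M1 or S1) of an oriented CgridMap
#'
#' @slot roi `"M1"` (precentral half, left columns of the oriented map) or
#'   `"S1"` (postcentral half, right columns).
#' @slot values numeric N x (M/2) matrix.
#' @slot mask logical matrix of the same shape.
#' @slot subject,hemisphere,task metadata carried over from the map.
#' @export
setClass("RoiSlice",
  representation(
    roi = "character",
    values = "matrix",
    mask = "matrix",
    subject = "character",
    hemisphere = "character",
    task = "character"
  )
)

setValidity("RoiSlice", function(object) {
  if (!object@roi %in% c("M1", "S1")) return("roi must be \"M1\" or \"S1\"")
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  TRUE
})
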