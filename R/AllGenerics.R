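#' @include AllClasses.R
NULL

#' Number of vertices / faces of a mesh
#' @param x a [FlatMesh-class].
#' @return integer count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Mesh accessors
#' @param x a [FlatMesh-class].
#' @return `meshVertices`: numeric matrix of xy coordinates; `meshFaces`:
#'   integer triangle matrix; `meshLabels`: character label vector.
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname meshVertices
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname meshVertices
#' @export
setGeneric("meshLabels", function(x) standardGeneric("meshLabels"))

#' Hemisphere tag of an object
#' @param x a [FlatMesh-class], [CgridDefinition-class] or [CgridMap-class].
#' @return `"left"` or `"right"`.
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' Grid dimensions
#' @param x a [CgridDefinition-class] or [CgridMap-class].
#' @return integer.
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname nRows
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' Tile values and validity mask of a grid map
#' @param x a [CgridMap-class] or [RoiSlice-class].
#' @return numeric (values) or logical (mask) matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' Border accessors
#' @param x a [Border-class] or [BorderSet-class].
#' @param role for `getBorder`, one of the five border roles.
#' @return `borderVertices`: integer vertex indices; `borderRole`: role
#'   string; `getBorder`: a [Border-class].
#' @export
setGeneric("borderVertices", function(x) standardGeneric("borderVertices"))

#' @rdname borderVertices
#' @export
setGeneric("borderRole", function(x) standardGeneric("borderRole"))

#' @rdname borderVertices
#' @export
setGeneric("getBorder", function(x, role) standardGeneric("getBorder"))

#' Pattern similarity between two grid maps
#'
#' Pearson correlation over tiles valid in both inputs, with the Fisher
#' z-transform (arctanh) applied after clamping r to +/-(1 - 1e-7).
#'
#' @param a,b two [CgridMap-class] objects, two [RoiSlice-class] objects, or
#'   two plain numeric matrices of identical shape (NAs treated as invalid).
#' @return a `similarityScore`: list with elements `r`, `z`, `nTiles`,
#'   `context`.
#' @seealso [fisherZ()], [inverseFisherZ()]
#' @export
setGeneric("pearsonSimilarity", function(a, b, ...) standardGeneric("pearsonSimilarity"))
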