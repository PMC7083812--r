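#' @include AllGenerics.R
NULL

#' Construct a FlatMesh
#'
#' @param vertices numeric matrix or data.frame with columns x, y (a.u.).
#' @param faces matrix of triangles, 3 vertex indices per row (1-based).
#' @param labels character vector, one ROI label per vertex.
#' @param hemisphere `"left"` or `"right"`.
#' @param metadata optional list.
#' @return a [FlatMesh-class] object.
#' @examples
#' m <- FlatMesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
#'               rbind(c(1, 2, 3)), c("A", "A", "B"), "left")
#' nVertices(m)
#' @export
FlatMesh <- function(vertices, faces, labels, hemisphere = "left",
                     metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  faces <- as.matrix(faces)
  if (length(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  new("FlatMesh", vertices = vertices, faces = faces,
      labels = as.character(labels), hemisphere = hemisphere,
      metadata = metadata)
}

#' @rdname nVertices
setMethod("nVertices", "FlatMesh", function(x) nrow(x@vertices))

#' @rdname nVertices
setMethod("nFaces", "FlatMesh", function(x) nrow(x@faces))

#' @rdname meshVertices
setMethod("meshVertices", "FlatMesh", function(x) x@vertices)

#' @rdname meshVertices
setMethod("meshFaces", "FlatMesh", function(x) x@faces)

#' @rdname meshVertices
setMethod("meshLabels", "FlatMesh", function(x) x@labels)

#' @rdname hemisphere
setMethod("hemisphere", "FlatMesh", function(x) x@hemisphere)

#' Ground-truth parametric coordinates of a synthetic mesh
#'
#' Synthetic subjects record each vertex's true (s, t) parametric position in
#' the band; real meshes return `NULL`. Intended for oracles and validation
#' only — nothing in the grid pipeline reads it.
#'
#' @param x a [FlatMesh-class].
#' @return a two-column matrix (s, t) or `NULL`.
#' @export
meshParametric <- function(x) x@metadata$parametric

setMethod("show", "FlatMesh", function(object) {
  cat(sprintf("FlatMesh: %d vertices, %d faces (%s hemisphere)\n",
              nVertices(object), nFaces(object), object@hemisphere))
  xr <- range(object@vertices[, 1]); yr <- range(object@vertices[, 2])
  cat(sprintf("  extent: x [%.2f, %.2f] a.u., y [%.2f, %.2f] a.u.\n",
              xr[1], xr[2], yr[1], yr[2]))
  labs <- sort(table(object@labels), decreasing = TRUE)
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s (%d)", names(labs)[seq_len(min(4, length(labs)))],
                            labs[seq_len(min(4, length(labs)))]), collapse = ", ")))
  if (length(labs) > 4) cat(sprintf("          ... and %d more\n", length(labs) - 4L))
})
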