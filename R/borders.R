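#' @include neighbors.R dialect.R
NULL

#' Extract the border between two labeled regions
#'
#' A border is the set of vertices labeled `L1` that have at least one mesh
#' neighbor labeled with a member of `L2set`. Borders are label-asymmetric:
#' the result contains only `L1`-labeled vertices.
#'
#' @param mesh a [FlatMesh-class].
#' @param neighbors optional neighbor table from [vertexNeighbors()]
#'   (computed on the fly when `NULL`).
#' @param L1 label (or labels) defining border membership.
#' @param L2set label or set of labels required on the other side.
#' @param role role string stored on the resulting border.
#' @return a [Border-class].
#' @examples
#' m <- FlatMesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
#'               rbind(c(1, 2, 3)), c("A", "A", "B"))
#' borderVertices(extractBorder(m, NULL, "A", "B"))
#' @export
extractBorder <- function(mesh, neighbors = NULL, L1, L2set, role = "custom") {
  if (is.null(neighbors)) neighbors <- vertexNeighbors(mesh)
  lab <- mesh@labels
  cand <- which(lab %in% L1)
  hit <- vapply(cand, function(v) any(lab[neighbors[[v]]] %in% L2set),
                logical(1))
  members <- cand[hit]
  if (!length(members))
    cgridStop(sprintf("empty border between {%s} and {%s}",
                      paste(L1, collapse = ", "),
                      paste(L2set, collapse = ", ")),
              "cgrid_empty_border_error")
  new("Border", role = role, vertices = as.integer(members))
}

#' @rdname borderVertices
setMethod("borderVertices", "Border", function(x) x@vertices)

#' @rdname borderVertices
setMethod("borderRole", "Border", function(x) x@role)

#' @rdname borderVertices
setMethod("getBorder", "BorderSet", function(x, role) x@borders[[role]])

setMethod("show", "Border", function(object) {
  cat(sprintf("Border '%s': %d vertices\n", object@role,
              length(object@vertices)))
})

setMethod("show", "BorderSet", function(object) {
  cat("BorderSet (sensorimotor):\n")
  for (b in object@borders)
    cat(sprintf("  %-18s %d vertices\n", b@role, length(b@vertices)))
})

# keep only the largest connected component of a border (label islands in
# real parcellations would wreck the polynomial fit)
.largestComponent <- function(border, neighbors) {
  comps <- .componentsOf(border@vertices, neighbors)
  if (length(comps) > 1L) {
    cgridWarn(sprintf(
      "border '%s' has %d connected components; keeping the largest (%d of %d vertices)",
      border@role, length(comps), length(comps[[1]]),
      length(border@vertices)))
    border@vertices <- comps[[1]]
  }
  border
}

#' Extract the five sensorimotor borders
#'
#' Builds the three vertical borders — central sulcus (precentral vs
#' postcentral), precentral sulcus (precentral vs pars opercularis / caudal
#' middle frontal / superior frontal), postcentral sulcus (postcentral vs
#' supramarginal / superior parietal) — and the two horizontal borders
#' bounding the sensorimotor strip: dorsal (vs paracentral lobule) and
#' ventral (vs insula). If a border splits into several connected components
#' under mesh adjacency, only the largest is kept, with a warning.
#'
#' @param mesh a validated [FlatMesh-class].
#' @param dialect a [labelDialect()] naming the nine regions on this mesh.
#' @return a [BorderSet-class].
#' @export
extractSmxBorders <- function(mesh, dialect = labelDialect("prose")) {
  dialect <- labelDialect(dialect)
  nbrs <- vertexNeighbors(mesh)
  ex <- function(L1, L2, role) {
    b <- tryCatch(extractBorder(mesh, nbrs, L1, L2, role = role),
                  cgrid_empty_border_error = function(e)
                    cgridStop(sprintf("border '%s' is empty (%s)", role,
                                      conditionMessage(e)),
                              "cgrid_empty_border_error"))
    .largestComponent(b, nbrs)
  }
  pre <- dialect[["precentral"]]; post <- dialect[["postcentral"]]
  borders <- list(
    central_sulcus = ex(pre, post, "central_sulcus"),
    precentral_sulcus = ex(pre, dialect[c("pars_opercularis",
                                          "caudal_middle_frontal",
                                          "superior_frontal")],
                           "precentral_sulcus"),
    postcentral_sulcus = ex(post, dialect[c("supramarginal",
                                            "superior_parietal")],
                            "postcentral_sulcus"),
    dorsal = ex(c(pre, post), dialect[["paracentral"]], "dorsal"),
    ventral = ex(c(pre, post), dialect[["insula"]], "ventral")
  )
  new("BorderSet", borders = borders, dialect = dialect)
}
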