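#' @include curves.R
NULL

#' @rdname nRows
setMethod("nRows", "CgridDefinition", function(x) x@nRows)

#' @rdname nRows
setMethod("nCols", "CgridDefinition", function(x) x@nCols)

#' @rdname hemisphere
setMethod("hemisphere", "CgridDefinition", function(x) x@hemisphere)

#' Resampled vertical curves of a grid definition
#' @param griddef a [CgridDefinition-class].
#' @return list of M+1 curve matrices, (N+1) x 2 each.
#' @export
gridCurves <- function(griddef) griddef@curves

#' Tile polygon and tile membership
#'
#' `tilePolygon` returns the quadrilateral of construction-space tile
#' `(r, c)` — row r from the ventral side, column c from the precentral
#' side — as a 4 x 2 matrix (curve-c node r, curve-c+1 node r, curve-c+1
#' node r+1, curve-c node r+1). `tileVertices` returns the mesh vertex
#' indices assigned to that tile.
#'
#' @param griddef a [CgridDefinition-class].
#' @param r,c 1-based construction row and column.
#' @export
tilePolygon <- function(griddef, r, c) {
  rbind(griddef@curves[[c]][r, ],
        griddef@curves[[c + 1L]][r, ],
        griddef@curves[[c + 1L]][r + 1L, ],
        griddef@curves[[c]][r + 1L, ])
}

#' @rdname tilePolygon
#' @export
tileVertices <- function(griddef, r, c) {
  which(griddef@assignment == (r - 1L) * griddef@nCols + c)
}

setMethod("show", "CgridDefinition", function(object) {
  cat(sprintf("CgridDefinition: %d x %d tiles (%s hemisphere)\n",
              object@nRows, object@nCols, object@hemisphere))
  cat(sprintf("  %d curves x %d nodes; y range [%.2f, %.2f] a.u.\n",
              length(object@curves), object@nRows + 1L,
              object@yRange[1], object@yRange[2]))
  cat(sprintf("  %d of %d vertices assigned to tiles (%d in the ROI)\n",
              sum(!is.na(object@assignment)), length(object@assignment),
              sum(object@smxVertex & !is.na(object@assignment))))
})

# assign every vertex to at most one tile. Tiles are visited in row-major
# (r, c) order and a vertex already assigned is never reassigned, which
# implements the deterministic boundary tie-break (smallest (row, column)
# wins). Point-in-polygon uses the even-odd rule with boundary counted as
# inside, so no convexity assumption is made.
.assignVertices <- function(mesh, curves, N, M) {
  vx <- mesh@vertices[, 1]; vy <- mesh@vertices[, 2]
  nv <- length(vx)
  assignment <- rep(NA_integer_, nv)
  extent <- max(diff(range(vx)), diff(range(vy)))
  eps <- 1e-9 * extent
  curveX <- vapply(curves, function(cc) cc[, 1], numeric(N + 1L))
  curveY <- vapply(curves, function(cc) cc[, 2], numeric(N + 1L))
  for (r in seq_len(N)) {
    ylo <- min(curveY[r, ], curveY[r + 1L, ]) - eps
    yhi <- max(curveY[r, ], curveY[r + 1L, ]) + eps
    rowCand <- which(is.na(assignment) & vy >= ylo & vy <= yhi)
    if (!length(rowCand)) next
    for (c in seq_len(M)) {
      qx <- c(curveX[r, c], curveX[r, c + 1L],
              curveX[r + 1L, c + 1L], curveX[r + 1L, c])
      qy <- c(curveY[r, c], curveY[r, c + 1L],
              curveY[r + 1L, c + 1L], curveY[r + 1L, c])
      cand <- rowCand[is.na(assignment[rowCand])]
      cand <- cand[vx[cand] >= min(qx) - eps & vx[cand] <= max(qx) + eps &
                   vy[cand] >= min(qy) - eps & vy[cand] <= max(qy) + eps]
      if (!length(cand)) next
      inside <- .pointInQuad(vx[cand], vy[cand], qx, qy, eps)
      if (any(inside))
        assignment[cand[inside]] <- (r - 1L) * M + c
    }
  }
  assignment
}

#' Build the Cartesian grid for one hemisphere
#'
#' Runs the full construction: order-10 polynomial fits through the three
#' vertical borders (on a shared centered/scaled ordinate), coefficient
#' interpolation into M+1 vertical curves sampled in unit steps over
#' `[y_min, y_max]`, truncation of each curve at the nodes nearest the
#' ventral and dorsal borders, equal-arc resampling into N segments, and
#' assignment of each mesh vertex to the enclosing tile.
#'
#' @param mesh a [FlatMesh-class].
#' @param borders a [BorderSet-class] from [extractSmxBorders()].
#' @param N number of rows (dorsoventral), default 28.
#' @param M number of columns (anteroposterior, even), default 84.
#' @param order polynomial order of the border fits.
#' @return a [CgridDefinition-class].
#' @examples
#' \donttest{
#' mesh <- makeSubjectFlatmap(subjectSpec(seed = 1, resolution = 2))
#' borders <- extractSmxBorders(mesh)
#' gd <- buildCgrid(mesh, borders, N = 14, M = 28)
#' gd
#' }
#' @export
buildCgrid <- function(mesh, borders, N = 28L, M = 84L, order = 10L) {
  N <- as.integer(N); M <- as.integer(M)
  if (M %% 2L != 0L)
    cgridStop("M must be even so the central sulcus sits at column M/2",
              "cgrid_config_error")
  yr <- computeYRange(borders, mesh)
  yc <- mean(yr); yh <- diff(yr) / 2
  fitPre <- fitVerticalBorder(getBorder(borders, "precentral_sulcus"), mesh,
                              order, yCenter = yc, yHalf = yh)
  fitCs <- fitVerticalBorder(getBorder(borders, "central_sulcus"), mesh,
                             order, yCenter = yc, yHalf = yh)
  fitPost <- fitVerticalBorder(getBorder(borders, "postcentral_sulcus"), mesh,
                               order, yCenter = yc, yHalf = yh)
  xExtent <- diff(range(mesh@vertices[, 1]))
  raw <- interpolateCoefficientCurves(fitPre, fitCs, fitPost, M,
                                      yr[1], yr[2], xExtent = xExtent)
  ven <- mesh@vertices[getBorder(borders, "ventral")@vertices, , drop = FALSE]
  dor <- mesh@vertices[getBorder(borders, "dorsal")@vertices, , drop = FALSE]
  curves <- vector("list", M + 1L)
  lens <- numeric(M + 1L)
  for (i in seq_along(raw)) {
    tc <- truncateCurve(raw[[i]], ven, dor)
    rs <- resampleEqualArc(tc, N)
    lens[i] <- attr(rs, "arcLength")
    attr(rs, "arcLength") <- NULL
    curves[[i]] <- rs
  }
  assignment <- .assignVertices(mesh, curves, N, M)
  dialect <- borders@dialect
  smx <- mesh@labels %in% dialect[c("precentral", "postcentral")]
  unassigned <- sum(smx & is.na(assignment))
  if (sum(smx) > 0 && unassigned > 0.10 * sum(smx))
    cgridWarn(sprintf(
      "%d of %d region-of-interest vertices (%.1f%%) fall outside every tile",
      unassigned, sum(smx), 100 * unassigned / sum(smx)))
  xRev <- mean(curves[[1L]][, 1]) > mean(curves[[M + 1L]][, 1])
  new("CgridDefinition", nRows = N, nCols = M, curves = curves,
      assignment = assignment, smxVertex = smx, yRange = yr,
      xReversed = xRev, hemisphere = mesh@hemisphere, curveLengths = lens)
}
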