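# Shared fixtures, built in code. Expensive ones are memoized per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# one triangle: vertices a=(0,0), b=(1,0), c=(0,1)
triMesh <- function(labels = c("A", "A", "B")) {
  FlatMesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(c(1, 2, 3)), labels)
}

# regular triangulated nx x ny grid with unit spacing; fixed diagonal so
# interior vertices have valence 6
regularGridMesh <- function(nx, ny, labels = NULL, spacing = 1) {
  x <- rep(seq_len(nx) - 1L, times = ny) * spacing
  y <- rep(seq_len(ny) - 1L, each = nx) * spacing
  i0 <- rep(seq_len(nx - 1L), times = ny - 1L) +
    rep((seq_len(ny - 1L) - 1L) * nx, each = nx - 1L)
  faces <- rbind(cbind(i0, i0 + 1L, i0 + nx),
                 cbind(i0 + 1L, i0 + nx + 1L, i0 + nx))
  if (is.null(labels)) labels <- rep("A", nx * ny)
  FlatMesh(cbind(x, y), faces, labels)
}

# coarse synthetic subject shared across files (moderate warp)
coarseSubject <- function() fixture("coarseSubject", function() {
  makeSubjectFlatmap(subjectSpec(seed = 42, resolution = 2, warpAmplitude = 3))
})

coarseBorders <- function() fixture("coarseBorders", function() {
  extractSmxBorders(coarseSubject())
})

coarseGrid <- function() fixture("coarseGrid", function() {
  buildCgrid(coarseSubject(), coarseBorders(), N = 14L, M = 28L)
})

# independent point-in-polygon oracle (crossing-number with boundary check),
# deliberately scalar and loop-based, unlike the vectorised implementation
oraclePointInPoly <- function(p, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    # on-segment check
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
    if (sum((p - (a + t * ab))^2) <= eps^2) return(TRUE)
    if ((b[2] > p[2]) != (a[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# brute-force row-major tile assignment using the oracle PIP
oracleAssign <- function(mesh, griddef) {
  v <- meshVertices(mesh)
  N <- nRows(griddef); M <- nCols(griddef)
  extent <- max(apply(v, 2, function(z) diff(range(z))))
  out <- rep(NA_integer_, nrow(v))
  for (r in seq_len(N)) for (c in seq_len(M)) {
    poly <- tilePolygon(griddef, r, c)
    for (k in seq_len(nrow(v))) {
      if (!is.na(out[k])) next
      if (oraclePointInPoly(v[k, ], poly, eps = 1e-9 * extent))
        out[k] <- (r - 1L) * M + c
    }
  }
  out
}

# construction-space tile (row from ventral, col from precentral) of a
# display-space position in an oriented map (caret convention)
displayToConstruction <- function(griddef, r, c) {
  rc <- nRows(griddef) + 1L - r
  flip <- xor(griddef@xReversed, hemisphere(griddef) == "right")
  cc <- if (flip) nCols(griddef) + 1L - c else c
  c(rc, cc)
}
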