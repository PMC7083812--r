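#' @include flatmesh.R
NULL

# directed edge list (both directions) from the face matrix
.edgeList <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0L) return(matrix(integer(0), 0L, 2L))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  rbind(e, e[, c(2, 1)])
}

#' Vertex adjacency of a flat mesh
#'
#' Two vertices are neighbors exactly when they share a face edge. The
#' relation is symmetric by construction.
#'
#' @param mesh a [FlatMesh-class].
#' @return a list of length `nVertices(mesh)`; element v is the sorted integer
#'   vector of neighbors of vertex v (empty for vertices in no face).
#' @examples
#' m <- FlatMesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
#'               rbind(c(1, 2, 3)), c("A", "A", "B"))
#' vertexNeighbors(m)[[1]]
#' @export
vertexNeighbors <- function(mesh) {
  nv <- nVertices(mesh)
  e <- .edgeList(mesh)
  out <- rep(list(integer(0)), nv)
  if (nrow(e) == 0L) return(out)
  key <- (e[, 1] - 1) * nv + e[, 2]
  e <- e[!duplicated(key), , drop = FALSE]
  sp <- split(e[, 2], e[, 1])
  idx <- as.integer(names(sp))
  out[idx] <- lapply(sp, function(v) sort(as.integer(v)))
  out
}

# row-normalized cotangent-weighted adjacency operator for diffusion
# smoothing. Cotangent weights are the standard isotropic discretization of
# the Laplace-Beltrami operator on a triangle mesh; uniform weights would
# bias diffusion along the dominant triangulation diagonal. Returns the
# operator together with the weighted per-axis mean squared neighbor
# displacement used to calibrate kernel width.
.adjacencyOperator <- function(mesh) {
  nv <- nVertices(mesh)
  f <- mesh@faces
  v <- mesh@vertices
  if (nrow(f) == 0L)
    return(list(W = Matrix::Diagonal(nv), msdAxis = NA_real_))
  cotAt <- function(a, b, c) {
    ux <- v[b, 1] - v[a, 1]; uy <- v[b, 2] - v[a, 2]
    wx <- v[c, 1] - v[a, 1]; wy <- v[c, 2] - v[a, 2]
    cr <- abs(ux * wy - uy * wx)
    ifelse(cr > 0, (ux * wx + uy * wy) / cr, 0)
  }
  i <- c(f[, 2], f[, 3], f[, 1])
  j <- c(f[, 3], f[, 1], f[, 2])
  cw <- pmax(c(cotAt(f[, 1], f[, 2], f[, 3]),
               cotAt(f[, 2], f[, 3], f[, 1]),
               cotAt(f[, 3], f[, 1], f[, 2])), 0)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(cw, 2),
                            dims = c(nv, nv))
  rs <- Matrix::rowSums(A)
  # vertices whose cotangent weights all vanish fall back to uniform weights
  zero <- which(rs <= 1e-12)
  if (length(zero)) {
    e <- .edgeList(mesh)
    e <- e[e[, 1] %in% zero, , drop = FALSE]
    if (nrow(e)) {
      e <- e[!duplicated((e[, 1] - 1) * nv + e[, 2]), , drop = FALSE]
      A <- A + Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                                    dims = c(nv, nv))
      rs <- Matrix::rowSums(A)
    }
    rs[rs <= 1e-12] <- 1
  }
  T <- as(A, "TsparseMatrix")
  ii <- T@i + 1L; jj <- T@j + 1L
  d2 <- (v[ii, 1] - v[jj, 1])^2 + (v[ii, 2] - v[jj, 2])^2
  msdAxis <- sum(T@x * d2) / sum(T@x) / 2
  list(W = Matrix::Diagonal(x = 1 / rs) %*% A, msdAxis = msdAxis)
}

#' Validate a labeled flat map
#'
#' Report-style checks run before grid construction: (i) presence of every
#' dialect label among the mesh labels, and (ii) central-sulcus orientation —
#' the principal axis of the precentral/postcentral boundary vertices must be
#' closer to vertical than horizontal (the grid procedure assumes the
#' dorsoventral axis runs along y).
#'
#' @param mesh a [FlatMesh-class].
#' @param dialect a [labelDialect()].
#' @return a list with elements `ok` (logical), `missingLabels` (character),
#'   `orientationOk` (logical, `NA` when the boundary is absent),
#'   `principalAngle` (radians from the y axis) and `messages`.
#' @export
validateFlatmap <- function(mesh, dialect = labelDialect("prose")) {
  msgs <- character(0)
  present <- unique(mesh@labels)
  missing <- unname(dialect[!dialect %in% present])
  if (length(missing))
    msgs <- c(msgs, paste0("missing label(s): ", paste(missing, collapse = ", ")))
  orientationOk <- NA
  angle <- NA_real_
  csb <- tryCatch(
    extractBorder(mesh, NULL, dialect[["precentral"]], dialect[["postcentral"]]),
    cgrid_error = function(e) NULL)
  if (!is.null(csb) && length(csb@vertices) >= 3L) {
    xy <- mesh@vertices[csb@vertices, , drop = FALSE]
    cv <- stats::cov(xy)
    ev <- eigen(cv, symmetric = TRUE)
    major <- ev$vectors[, 1]
    # angle between the major axis and the vertical
    angle <- acos(min(1, abs(major[2]) / sqrt(sum(major^2))))
    orientationOk <- angle < pi / 4
    if (!orientationOk)
      msgs <- c(msgs, sprintf(
        "central sulcus is not vertical (principal axis %.0f deg off the y axis)",
        angle * 180 / pi))
  } else {
    msgs <- c(msgs, "central sulcus boundary absent; orientation not checked")
  }
  list(ok = length(missing) == 0L && isTRUE(orientationOk),
       missingLabels = missing,
       orientationOk = orientationOk,
       principalAngle = angle,
       messages = msgs)
}
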