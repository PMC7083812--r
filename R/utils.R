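# internal helpers: error conditions, seeded evaluation, small geometry

cgridStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cgrid_error", "error")))
}

cgridWarn <- function(msg, class = "cgrid_warning") {
  warning(warningCondition(msg, class = c(class, "warning")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# squared euclidean distances between a set of points and one point
.dist2 <- function(xy, p) {
  (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
}

# polyline length
.polylineLength <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# vectorised even-odd point-in-quadrilateral test; points on the boundary
# (within eps) count as inside, so that the caller's first-tested tile claims them
.pointInQuad <- function(px, py, qx, qy, eps) {
  n <- length(qx)
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- qx[i]; yi <- qy[i]; xj <- qx[j]; yj <- qy[j]
    # boundary proximity to segment (j -> i)
    ex <- xi - xj; ey <- yi - yj
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - xj) * ex + (py - yj) * ey) / len2))
      dx <- px - (xj + t * ex); dy <- py - (yj + t * ey)
      onb <- onb | (dx * dx + dy * dy <= eps * eps)
    } else {
      onb <- onb | ((px - xj)^2 + (py - yj)^2 <= eps * eps)
    }
    cross <- ((yi > py) != (yj > py))
    if (any(cross)) {
      xint <- xj + (py - yj) * (xi - xj) / (yi - yj)
      inside <- xor(inside, cross & (px < xint))
    }
    j <- i
  }
  inside | onb
}

# connected components of a vertex subset under mesh adjacency; returns a list
# of integer vectors (vertex ids), largest first
.componentsOf <- function(members, nbrs) {
  inset <- logical(max(c(members, 1L)))
  inset[members] <- TRUE
  seen <- logical(length(inset))
  comps <- list()
  for (v in members) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      ws <- nbrs[[u]]
      ws <- ws[ws <= length(inset) & inset[ws] & !seen[ws]]
      if (length(ws)) {
        seen[ws] <- TRUE
        queue <- c(queue, ws)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, length, integer(1)), decreasing = TRUE)]
}
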