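#' @include polyfit.R
NULL

#' Dorsoventral extent of the sensorimotor strip
#'
#' `y_min` is the smallest y over the ventral border, `y_max` the largest y
#' over the dorsal border, so the vertical curves cover the whole strip.
#'
#' @param borders a [BorderSet-class].
#' @param mesh the source [FlatMesh-class].
#' @return numeric `c(yMin, yMax)`.
#' @export
computeYRange <- function(borders, mesh) {
  vy <- mesh@vertices[, 2]
  yMin <- min(vy[getBorder(borders, "ventral")@vertices])
  yMax <- max(vy[getBorder(borders, "dorsal")@vertices])
  if (yMin >= yMax)
    cgridStop(sprintf(
      "degenerate dorsoventral range [%.3f, %.3f]; is the mesh upside-down?",
      yMin, yMax), "cgrid_geometry_error")
  c(yMin, yMax)
}

#' Interpolate vertical curves between the three border fits
#'
#' Generates M+1 vertical curves by linear interpolation of the 11 polynomial
#' coefficients: columns 0..M/2 run from the precentral fit to the central
#' sulcus fit, columns M/2..M from the central sulcus to the postcentral fit,
#' so column M/2 is the central sulcus exactly. Each curve is the
#' interpolated polynomial evaluated from `yMin` to `yMax` in unit (1 a.u.)
#' steps, extrapolating the fits where needed. The three fits must share
#' their scaled basis; they are re-expressed exactly in a common basis on
#' `[yMin, yMax]` first.
#'
#' @param fitPre,fitCs,fitPost `borderFit`s of the precentral, central-sulcus
#'   and postcentral borders.
#' @param M number of columns; must be even, at least 2.
#' @param yMin,yMax dorsoventral range (see [computeYRange()]).
#' @param xExtent optional guard: error out when an extrapolated |x| exceeds
#'   3 times this value (runaway order-10 extrapolation).
#' @return list of M+1 curve matrices (columns `x`, `y`, nodes ordered
#'   ventral to dorsal), with the (M+1) x 11 coefficient matrix in
#'   `attr(, "coefficients")`.
#' @export
interpolateCoefficientCurves <- function(fitPre, fitCs, fitPost, M,
                                         yMin, yMax, xExtent = NULL) {
  if (M %% 2L != 0L || M < 2L)
    cgridStop("the number of columns M must be an even integer >= 2",
              "cgrid_config_error")
  yc <- (yMin + yMax) / 2
  yh <- (yMax - yMin) / 2
  fits <- lapply(list(fitPre, fitCs, fitPost), .rebaseFit,
                 yCenter = yc, yHalf = yh)
  y <- seq(yMin, yMax, by = 1)
  if (y[length(y)] < yMax) y <- c(y, yMax)
  t <- (y - yc) / yh
  half <- M / 2L
  coefMat <- matrix(NA_real_, M + 1L, length(fits[[1]]$coef))
  curves <- vector("list", M + 1L)
  for (i in 0:M) {
    if (i <= half) {
      w <- i / half
      coef <- (1 - w) * fits[[1]]$coef + w * fits[[2]]$coef
    } else {
      w <- (i - half) / half
      coef <- (1 - w) * fits[[2]]$coef + w * fits[[3]]$coef
    }
    x <- .polyEval(coef, t)
    if (!is.null(xExtent) && any(abs(x) > 3 * xExtent))
      cgridStop(sprintf(
        "curve %d extrapolates to |x| = %.1f, beyond 3x the mesh extent",
        i, max(abs(x))), "cgrid_geometry_error")
    coefMat[i + 1L, ] <- coef
    curves[[i + 1L]] <- cbind(x = x, y = y)
  }
  attr(curves, "coefficients") <- coefMat
  attr(curves, "basis") <- c(yCenter = yc, yHalf = yh)
  curves
}

# index of the curve node nearest to any of the given points
.nearestNode <- function(curve, pts) {
  d2 <- outer(curve[, 1], pts[, 1], `-`)^2 + outer(curve[, 2], pts[, 2], `-`)^2
  which.min(apply(d2, 1L, min))
}

#' Truncate a vertical curve at the ventral and dorsal borders
#'
#' Cuts the curve at the nodes closest (Euclidean) to any vertex of the
#' ventral and dorsal borders, keeping the sub-curve between the two cut
#' nodes inclusive, ventral node first.
#'
#' @param curve curve matrix (columns x, y).
#' @param ventral,dorsal [Border-class] objects or plain point matrices.
#' @param mesh the source mesh (needed when borders are [Border-class]).
#' @return the truncated curve matrix.
#' @export
truncateCurve <- function(curve, ventral, dorsal, mesh = NULL) {
  asPts <- function(b) {
    if (is(b, "Border")) {
      if (is.null(mesh))
        cgridStop("mesh required when truncating with Border objects",
                  "cgrid_config_error")
      mesh@vertices[b@vertices, , drop = FALSE]
    } else as.matrix(b)
  }
  if (nrow(curve) < 2L)
    cgridStop("curve must have at least 2 nodes", "cgrid_geometry_error")
  iVen <- .nearestNode(curve, asPts(ventral))
  iDor <- .nearestNode(curve, asPts(dorsal))
  if (iVen == iDor)
    cgridStop("ventral and dorsal cuts fall on the same node; curve is degenerate",
              "cgrid_degenerate_error")
  curve[iVen:iDor, , drop = FALSE]
}

#' Resample a curve at equal arc length
#'
#' The polyline is (conceptually) densified to ~0.1 a.u. node spacing, its
#' length computed as the sum of node-to-node distances, and N+1 nodes are
#' placed at arc-length positions `0, l/N, ..., l`. For a piecewise-linear
#' curve the densification leaves both the length and the interpolated node
#' positions unchanged, so the resampling is performed by exact linear
#' interpolation along the polyline; endpoints are preserved exactly.
#'
#' @param curve curve matrix (columns x, y), ventral node first.
#' @param N number of segments (tiles rows); N+1 nodes are returned.
#' @return (N+1) x 2 matrix with attribute `arcLength`.
#' @export
resampleEqualArc <- function(curve, N) {
  if (N < 1L)
    cgridStop("N must be at least 1", "cgrid_config_error")
  seg <- sqrt(diff(curve[, 1])^2 + diff(curve[, 2])^2)
  L <- sum(seg)
  if (!is.finite(L) || L <= 0)
    cgridStop("zero-length curve cannot be resampled", "cgrid_degenerate_error")
  cum <- c(0, cumsum(seg))
  targets <- seq(0, L, length.out = N + 1L)
  xs <- stats::approx(cum, curve[, 1], xout = targets, ties = "ordered")$y
  ys <- stats::approx(cum, curve[, 2], xout = targets, ties = "ordered")$y
  out <- cbind(x = xs, y = ys)
  out[1, ] <- curve[1, ]
  out[N + 1L, ] <- curve[nrow(curve), ]
  attr(out, "arcLength") <- L
  out
}
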