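#' @include borders.R
NULL

# Polynomial fits are carried out on a centered, scaled ordinate
# t = (y - yCenter) / yHalf, because raw order-10 monomial fits on
# coordinates in the tens-to-hundreds are numerically unstable.
# Coefficients are stored ascending (c0 ... c_order) in that basis.

.polyEval <- function(coef, t) {
  out <- rep(coef[length(coef)], length(t))
  for (k in rev(seq_len(length(coef) - 1L)))
    out <- out * t + coef[k]
  out
}

# exact change of variable: q(u) = p(a*u + b), monomial coefficients ascending
.polyCompose <- function(coef, a, b) {
  q <- coef[length(coef)]
  for (k in rev(seq_len(length(coef) - 1L))) {
    # q <- q * (a*u + b) + c_k
    qa <- c(0, q * a)
    qb <- c(q * b, 0)
    q <- qa + qb
    q[1] <- q[1] + coef[k]
  }
  q
}

#' Fit a polynomial through a vertical border
#'
#' Least-squares fit of x as a function of y through the border vertices
#' (the dorsoventral coordinate is the independent variable). Order 10
#' balances capturing border shape against stable extrapolation.
#'
#' @param border a [Border-class].
#' @param mesh the source [FlatMesh-class].
#' @param order polynomial order (default 10, i.e. 11 coefficients).
#' @param yCenter,yHalf basis of the internal scaled ordinate
#'   `t = (y - yCenter)/yHalf`; default centers and scales the border's own
#'   y-range to `[-1, 1]`. [buildCgrid()] passes a basis shared by the three
#'   fits so their coefficients can be interpolated.
#' @return a `borderFit`: list with `coef` (ascending, in the scaled basis),
#'   `yDomain`, `yCenter`, `yHalf`, `role`.
#' @seealso [evalBorderFit()], [interpolateCoefficientCurves()]
#' @export
fitVerticalBorder <- function(border, mesh, order = 10L,
                              yCenter = NULL, yHalf = NULL) {
  xy <- mesh@vertices[border@vertices, , drop = FALSE]
  if (nrow(xy) <= order + 1L)
    cgridStop(sprintf(
      "border '%s' has %d vertices; an order-%d fit needs more than %d",
      border@role, nrow(xy), order, order + 1L), "cgrid_fit_error")
  ylo <- min(xy[, 2]); yhi <- max(xy[, 2])
  if (is.null(yCenter)) yCenter <- (ylo + yhi) / 2
  if (is.null(yHalf)) yHalf <- (yhi - ylo) / 2
  if (yHalf <= 0)
    cgridStop(sprintf("border '%s' is degenerate in y", border@role),
              "cgrid_fit_error")
  t <- (xy[, 2] - yCenter) / yHalf
  X <- outer(t, 0:order, `^`)
  qrX <- qr(X)
  if (qrX$rank < order + 1L)
    cgridStop(sprintf(
      "rank-deficient fit for border '%s' (rank %d < %d); too few distinct y values",
      border@role, qrX$rank, order + 1L), "cgrid_fit_error")
  coef <- qr.coef(qrX, xy[, 1])
  structure(list(coef = unname(coef), yDomain = c(ylo, yhi),
                 yCenter = yCenter, yHalf = yHalf, role = border@role),
            class = "borderFit")
}

#' Evaluate a border fit at given y
#'
#' @param fit a `borderFit` from [fitVerticalBorder()].
#' @param y numeric vector of dorsoventral coordinates (a.u.); values outside
#'   the fit domain extrapolate with the same polynomial.
#' @return fitted x coordinates.
#' @export
evalBorderFit <- function(fit, y) {
  .polyEval(fit$coef, (y - fit$yCenter) / fit$yHalf)
}

# re-express a fit's coefficients in another centered/scaled basis, exactly
.rebaseFit <- function(fit, yCenter, yHalf) {
  a <- yHalf / fit$yHalf
  b <- (yCenter - fit$yCenter) / fit$yHalf
  fit$coef <- .polyCompose(fit$coef, a, b)
  fit$yCenter <- yCenter
  fit$yHalf <- yHalf
  fit
}
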