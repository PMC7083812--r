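# standalone border/mesh pair on isolated vertices (fits don't need faces)
pointBorder <- function(x, y, role = "central_sulcus") {
  mesh <- FlatMesh(cbind(x, y), matrix(integer(0), 0, 3),
                   rep("Precentral gyrus", length(x)))
  list(mesh = mesh,
       border = new("Border", role = role, vertices = seq_along(x)))
}

test_that("vertical border fits recover constant, linear and noisy shapes", {
  pb <- pointBorder(rep(3, 21), 0:20)
  fit <- fitVerticalBorder(pb$border, pb$mesh)
  expect_equal(evalBorderFit(fit, c(0, 7.3, 20)), rep(3, 3), tolerance = 1e-6)

  pb <- pointBorder(2 * (0:20), 0:20)
  fit <- fitVerticalBorder(pb$border, pb$mesh)
  expect_equal(evalBorderFit(fit, 10), 20, tolerance = 1e-6)

  # noisy sinusoid: compare with an independent normal-equations solve on
  # the same centered/scaled ordinate
  set.seed(99)
  y <- seq(0, 40, length.out = 80)
  x <- 5 * sin(y / 7) + rnorm(80, 0, 0.1)
  pb <- pointBorder(x, y)
  fit <- fitVerticalBorder(pb$border, pb$mesh)
  t <- (y - mean(range(y))) / (diff(range(y)) / 2)
  X <- outer(t, 0:10, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  expect_equal(evalBorderFit(fit, y), as.vector(X %*% beta), tolerance = 1e-6)

  # underdetermined and rank-deficient systems are named errors
  pb <- pointBorder(1:5, 1:5)
  expect_error(fitVerticalBorder(pb$border, pb$mesh), class = "cgrid_fit_error")
  pb <- pointBorder(1:30, rep(1:3, 10))  # only 3 distinct y values
  expect_error(fitVerticalBorder(pb$border, pb$mesh), class = "cgrid_fit_error")
})

test_that("the dorsoventral range comes from the ventral/dorsal borders and covers the strip", {
  mkBorders <- function(venY, dorY) {
    n <- length(venY) + length(dorY)
    mesh <- FlatMesh(cbind(seq_len(n), c(venY, dorY)),
                     matrix(integer(0), 0, 3), rep("x", n))
    mk <- function(role, idx) new("Border", role = role, vertices = as.integer(idx))
    bs <- new("BorderSet", borders = list(
      central_sulcus = mk("central_sulcus", 1L),
      precentral_sulcus = mk("precentral_sulcus", 1L),
      postcentral_sulcus = mk("postcentral_sulcus", 1L),
      ventral = mk("ventral", seq_along(venY)),
      dorsal = mk("dorsal", length(venY) + seq_along(dorY))),
      dialect = labelDialect("prose"))
    list(mesh = mesh, bs = bs)
  }
  ok <- mkBorders(c(0, 1), c(9, 10))
  expect_equal(computeYRange(ok$bs, ok$mesh), c(0, 10))
  bad <- mkBorders(5, 5)
  expect_error(computeYRange(bad$bs, bad$mesh), class = "cgrid_geometry_error")

  # coverage scan: every ROI vertex lies within [y_min, y_max] +/- one edge
  mesh <- coarseSubject()
  yr <- computeYRange(coarseBorders(), mesh)
  smx <- meshLabels(mesh) %in% c("Precentral gyrus", "Postcentral gyrus")
  vy <- meshVertices(mesh)[smx, 2]
  edge <- 2
  expect_true(all(vy >= yr[1] - edge & vy <= yr[2] + edge))
})

test_that("coefficient interpolation pins the endpoints, midpoints and parallel lines", {
  mk <- function(x) {
    pb <- pointBorder(x, seq(0, 20, length.out = 40))
    fitVerticalBorder(pb$border, pb$mesh, yCenter = 10, yHalf = 10)
  }
  set.seed(4)
  fitPre <- mk(0.5 * sin(seq(0, 3, length.out = 40)) + 2)
  fitCs <- mk(rep(10, 40))
  fitPost <- mk(seq(18, 22, length.out = 40))
  cur <- interpolateCoefficientCurves(fitPre, fitCs, fitPost, M = 4,
                                      yMin = 0, yMax = 20)
  expect_length(cur, 5L)
  y <- cur[[1]][, 2]
  # column 0 is exactly the precentral fit on the y lattice
  expect_equal(cur[[1]][, 1], evalBorderFit(fitPre, y), tolerance = 1e-9)
  # column M/2 is exactly the central-sulcus fit
  expect_equal(cur[[3]][, 1], evalBorderFit(fitCs, y), tolerance = 1e-9)
  # column 1 coefficients are the elementwise mean of pre and cs
  coefs <- attr(cur, "coefficients")
  expect_equal(coefs[2, ], (coefs[1, ] + coefs[3, ]) / 2, tolerance = 1e-12)

  # three parallel vertical lines x = 0, 10, 20 -> curves at 0, 5, 10, 15, 20
  fits <- lapply(c(0, 10, 20), function(x0) mk(rep(x0, 40)))
  cur <- interpolateCoefficientCurves(fits[[1]], fits[[2]], fits[[3]], M = 4,
                                      yMin = 0, yMax = 20)
  for (i in 1:5)
    expect_equal(unname(cur[[i]][, 1]), rep((i - 1) * 5, length(y)),
                 tolerance = 1e-8)

  expect_error(interpolateCoefficientCurves(fitPre, fitCs, fitPost, M = 5,
                                            yMin = 0, yMax = 20),
               class = "cgrid_config_error")
})

test_that("fits from different bases interpolate identically after rebasing", {
  # the same geometry fitted on its own domain vs a shared basis must yield
  # the same interpolated curves (exact polynomial change of variable)
  y <- seq(3, 37, length.out = 60)
  x <- 4 * cos(y / 9)
  pb <- pointBorder(x, y)
  own <- fitVerticalBorder(pb$border, pb$mesh)
  reb <- cgrid:::.rebaseFit(own, 10, 30)
  yy <- seq(3, 37, length.out = 17)
  expect_equal(evalBorderFit(reb, yy), evalBorderFit(own, yy),
               tolerance = 1e-8)
})

test_that("curve truncation picks the nodes nearest the horizontal borders", {
  curve <- cbind(x = rep(0, 101), y = 0:100)
  # a border vertex coinciding with node 8 (y = 7) cuts there exactly
  tr <- truncateCurve(curve, rbind(c(0, 7)), rbind(c(0, 93)))
  expect_equal(tr[1, ], c(x = 0, y = 7))
  expect_equal(tr[nrow(tr), ], c(x = 0, y = 93))

  # single-vertex border: exhaustive nearest-node scan oracle
  set.seed(12)
  wig <- cbind(x = cumsum(rnorm(60, 0, 0.4)), y = seq(0, 80, length.out = 60))
  p <- c(3, 22.7)
  tr <- truncateCurve(wig, rbind(p), rbind(wig[60, ]))
  d <- sqrt((wig[, 1] - p[1])^2 + (wig[, 2] - p[2])^2)
  expect_equal(unname(tr[1, ]), unname(wig[which.min(d), ]))

  # straight-line geometry: ven near y=20, dor near y=80 -> spans ~[20, 80]
  ven <- cbind(runif(5, -1, 1), 20 + runif(5, -0.3, 0.3))
  dor <- cbind(runif(5, -1, 1), 80 + runif(5, -0.3, 0.3))
  tr <- truncateCurve(curve, ven, dor)
  expect_lt(abs(tr[1, 2] - 20), 1)
  expect_lt(abs(tr[nrow(tr), 2] - 80), 1)

  expect_error(truncateCurve(curve, rbind(c(0, 50)), rbind(c(0.2, 50))),
               class = "cgrid_degenerate_error")
})

test_that("equal-arc resampling preserves endpoints and matches quadrature", {
  seg <- cbind(x = rep(0, 11), y = 0:10)
  rs <- resampleEqualArc(seg, 5)
  expect_equal(unname(rs[, 2]), c(0, 2, 4, 6, 8, 10))
  expect_equal(attr(rs, "arcLength"), 10)

  expect_equal(nrow(resampleEqualArc(seg, 1)), 2L)
  expect_equal(unname(resampleEqualArc(seg, 1)[2, ]), c(0, 10))

  # quarter circle of radius 10 sampled in ~unit steps
  th <- seq(0, pi / 2, length.out = 17)
  qc <- cbind(x = 10 * cos(th), y = 10 * sin(th))
  rs <- resampleEqualArc(qc, 7)
  expect_lt(abs(attr(rs, "arcLength") - 5 * pi) / (5 * pi), 0.002)
  sp <- sqrt(diff(rs[, 1])^2 + diff(rs[, 2])^2)
  expect_lt(diff(range(sp)) / mean(sp), 1e-3)

  expect_error(resampleEqualArc(seg[1:1, , drop = FALSE], 3),
               class = "cgrid_degenerate_error")
})

test_that("grid construction yields the advertised tile/curve/node counts", {
  gd <- coarseGrid()
  expect_equal(nRows(gd), 14L)
  expect_equal(nCols(gd), 28L)
  expect_length(gridCurves(gd), 29L)
  expect_true(all(vapply(gridCurves(gd), nrow, integer(1)) == 15L))
  expect_error(buildCgrid(coarseSubject(), coarseBorders(), N = 4, M = 7),
               class = "cgrid_config_error")
})

test_that("tile assignment agrees with an exhaustive point-in-polygon oracle", {
  mesh <- coarseSubject()
  gd <- coarseGrid()
  v <- meshVertices(mesh)
  set.seed(7)
  assigned <- which(!is.na(gd@assignment))
  sample_v <- sample(assigned, 60)
  extent <- max(apply(v, 2, function(z) diff(range(z))))
  for (k in sample_v) {
    hits <- integer(0)
    for (r in seq_len(nRows(gd))) for (c in seq_len(nCols(gd))) {
      if (oraclePointInPoly(v[k, ], tilePolygon(gd, r, c),
                            eps = 1e-9 * extent))
        hits <- c(hits, (r - 1L) * nCols(gd) + c)
    }
    # the assigned tile must be among the enclosing tiles, and the
    # row-major-first tie-break picks the smallest id
    expect_true(gd@assignment[k] %in% hits)
    expect_equal(gd@assignment[k], min(hits))
  }
  # unassigned sampled vertices are enclosed by no tile
  un <- sample(which(is.na(gd@assignment)), 20)
  for (k in un) {
    inside <- FALSE
    for (r in seq_len(nRows(gd))) for (c in seq_len(nCols(gd)))
      if (oraclePointInPoly(v[k, ], tilePolygon(gd, r, c),
                            eps = 1e-9 * extent)) inside <- TRUE
    expect_false(inside)
  }
})

test_that("grid geometry invariants hold: equal arcs, pinned sulcus, ordering, partition", {
  mesh <- coarseSubject()
  gd <- coarseGrid()
  # equal-arc spacing within each curve
  for (cur in gridCurves(gd)) {
    sp <- sqrt(diff(cur[, 1])^2 + diff(cur[, 2])^2)
    expect_lt(diff(range(sp)) / mean(sp), 1e-2)
  }
  # column M/2 carries the central-sulcus polynomial: its nodes hug the
  # central-sulcus border vertices
  csXY <- meshVertices(mesh)[borderVertices(getBorder(coarseBorders(),
                                                      "central_sulcus")), ]
  mid <- gridCurves(gd)[[nCols(gd) / 2 + 1L]]
  d <- vapply(seq_len(nrow(mid)), function(i)
    sqrt(min((csXY[, 1] - mid[i, 1])^2 + (csXY[, 2] - mid[i, 2])^2)),
    numeric(1))
  expect_lt(max(d), 2 * 2)  # within ~2 edge lengths everywhere
  # monotone column ordering at every row (no curve crossings)
  xs <- vapply(gridCurves(gd), function(cc) cc[, 1], numeric(nRows(gd) + 1L))
  ord <- apply(xs, 1L, function(row) all(diff(row) > 0) || all(diff(row) < 0))
  expect_true(all(ord))
  # each vertex sits in at most one tile by representation; ids are in range
  expect_true(all(is.na(gd@assignment) |
                  (gd@assignment >= 1L & gd@assignment <= 14L * 28L)))
})

test_that("x-reflection of the mesh column-reverses the mapped grid", {
  mesh <- coarseSubject()
  gd <- coarseGrid()
  field <- makeActivation(mesh, taskHotspots("hand_right", "left"),
                          noiseSd = 0)
  mapL <- orientGrid(mapToGrid(field, gd))

  refl <- mesh
  refl@vertices <- cbind(x = -mesh@vertices[, 1], y = mesh@vertices[, 2])
  refl@hemisphere <- "right"
  gdR <- buildCgrid(refl, extractSmxBorders(refl), N = 14L, M = 28L)
  mapR <- orientGrid(mapToGrid(field, gdR))
  # after orientation the reflected subject matches the original map
  joint <- gridMask(mapL) & gridMask(mapR)
  same <- abs(gridValues(mapL)[joint] - gridValues(mapR)[joint]) < 1e-9
  expect_gt(mean(same), 0.95)
  expect_lt(max(abs(gridPeak(mapL) - gridPeak(mapR))), 2)
})
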