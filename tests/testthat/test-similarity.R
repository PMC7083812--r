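mkMap <- function(vals, hemi = "left", subject = "s", task = "feet",
                  oriented = TRUE, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(vals)
  vals[!mask] <- NA_real_
  new("CgridMap", values = vals, mask = mask, subject = subject,
      hemisphere = hemi, task = task, field = "f", oriented = oriented)
}

test_that("pearson similarity matches the textbook formula on masked values", {
  set.seed(2)
  a <- matrix(rnorm(28 * 84), 28, 84)
  b <- matrix(rnorm(28 * 84), 28, 84)
  mask <- matrix(runif(28 * 84) < 0.8, 28, 84)
  a[!mask] <- NA; b[!mask] <- NA
  sc <- pearsonSimilarity(a, b)
  # oracle: covariance over sigma-sigma from explicit sums
  x <- a[mask]; y <- b[mask]; n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt(sum(x^2) - n * mean(x)^2) * sqrt(sum(y^2) - n * mean(y)^2)
  expect_equal(sc$r, num / den, tolerance = 1e-12)
  expect_equal(sc$nTiles, n)
  expect_equal(sc$z, atanh(sc$r), tolerance = 1e-12)

  # self- and anti-correlation engage the clamp
  self <- pearsonSimilarity(mkMap(a), mkMap(a))
  expect_equal(self$r, 1)
  expect_equal(self$z, atanh(1 - 1e-7))
  anti <- pearsonSimilarity(mkMap(a), mkMap(-a))
  expect_equal(anti$r, -1)
  expect_equal(anti$z, -atanh(1 - 1e-7))

  # degenerate inputs raise named errors
  few <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(pearsonSimilarity(few, few), class = "cgrid_degenerate_error")
  flat <- matrix(1, 3, 3)
  expect_error(pearsonSimilarity(flat, matrix(rnorm(9), 3, 3)),
               class = "cgrid_degenerate_error")
  expect_error(pearsonSimilarity(a, matrix(rnorm(4), 2, 2)),
               class = "cgrid_shape_error")
})

test_that("Fisher z is an increasing involution with tanh and hits the printed pairs", {
  rs <- seq(-0.999, 0.999, length.out = 41)
  expect_equal(inverseFisherZ(fisherZ(rs)), rs, tolerance = 1e-12)
  expect_true(all(diff(fisherZ(rs)) > 0))
  expect_equal(inverseFisherZ(0), 0)
  # affine invariance of r (positive slope)
  set.seed(3)
  a <- matrix(rnorm(100), 10, 10); b <- matrix(rnorm(100), 10, 10)
  r0 <- pearsonSimilarity(a, b)$r
  expect_equal(pearsonSimilarity(3 * a + 7, 0.2 * b - 4)$r, r0,
               tolerance = 1e-12)
})

test_that("within-subject scores pair hemispheres and tasks as specified", {
  set.seed(6)
  base <- matrix(rnorm(8 * 12), 8, 12)
  maps <- list()
  for (task in c("feet", "tongue", "hand_left", "hand_right"))
    for (h in c("left", "right"))
      maps[[paste(task, h)]] <- mkMap(base, hemi = h, task = task)
  # identical patterns across hemispheres: all six z at the clamp value
  ws <- withinSubjectScores(maps)
  expect_equal(nrow(ws$scores), 6L)
  expect_true(all(abs(ws$scores$z - atanh(1 - 1e-7)) < 1e-12))
  expect_equal(ws$aggregate, atanh(1 - 1e-7), tolerance = 1e-12)

  # the hand score correlates left-hemisphere hand_right with
  # right-hemisphere hand_left (contralateral pairing)
  maps2 <- maps
  hrL <- matrix(rnorm(8 * 12), 8, 12)
  maps2[["hand_right left"]] <- mkMap(hrL, hemi = "left", task = "hand_right")
  hlR <- 2 * hrL + 1  # perfectly correlated with hand_right left
  maps2[["hand_left right"]] <- mkMap(hlR, hemi = "right", task = "hand_left")
  # scrambling the ipsilateral maps must not affect the hand score
  maps2[["hand_left left"]] <- mkMap(matrix(rnorm(96), 8, 12),
                                     hemi = "left", task = "hand_left")
  maps2[["hand_right right"]] <- mkMap(matrix(rnorm(96), 8, 12),
                                       hemi = "right", task = "hand_right")
  ws2 <- withinSubjectScores(maps2)
  hand <- ws2$scores[ws2$scores$task == "hand", ]
  expect_true(all(hand$r > 1 - 1e-12))

  expect_error(withinSubjectScores(maps[1:5]),
               class = "cgrid_missing_map_error")
  un <- maps; un[[1]]@oriented <- FALSE
  expect_error(withinSubjectScores(un), class = "cgrid_config_error")
})

test_that("mirrored somatotopy scores above independently placed hotspots", {
  mkSubj <- function(seed, mirrored) {
    maps <- list()
    withSeedDraw <- function(k) {
      set.seed(seed + k)
      data.frame(s = runif(1, 0.2, 0.8), t = runif(1, 0.2, 0.8),
                 amplitude = 1, width = 0.08)
    }
    k <- 0
    for (task in c("feet", "tongue", "hand_left", "hand_right")) {
      hsL <- withSeedDraw(k); k <- k + 1
      hsR <- if (mirrored) hsL else withSeedDraw(k + 100)
      k <- k + 1
      for (h in c("left", "right")) {
        spec <- subjectSpec(seed = seed + match(h, c("left", "right")),
                            resolution = 2, warpAmplitude = 3, hemisphere = h)
        mesh <- makeSubjectFlatmap(spec)
        gd <- buildCgrid(mesh, extractSmxBorders(mesh), N = 14L, M = 28L)
        hs <- if (h == "left") hsL else hsR
        f <- smoothVertexField(makeActivation(mesh, hs, noiseSd = 0.05,
                                              seed = seed + k), mesh, 4)
        maps[[paste(task, h)]] <- orientGrid(
          mapToGrid(f, gd, subject = "s", task = task))
      }
    }
    withinSubjectScores(maps)$aggregate
  }
  expect_gt(mkSubj(400, TRUE), mkSubj(400, FALSE))
})

test_that("leave-one-out scores match a hand-rolled small-case oracle", {
  # homogeneous cohort: every leave-one-out r is 1 (z clamped)
  set.seed(9)
  shared <- matrix(rnorm(9), 3, 3)
  maps <- lapply(1:4, function(i) mkMap(shared, subject = paste0("S", i)))
  loo <- betweenSubjectLoo(maps)
  expect_true(all(loo$r == 1))
  expect_true(all(loo$z == atanh(1 - 1e-7)))

  # 3 subjects, small maps, partial masks: brute-force loops
  vals <- list(matrix(c(1, 2, 3, 4, 5, 6), 2, 3),
               matrix(c(2, 1, 4, 3, 6, 5), 2, 3),
               matrix(c(1, 1, 2, 5, 3, 8), 2, 3))
  masks <- list(matrix(TRUE, 2, 3),
                matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3),
                matrix(TRUE, 2, 3))
  maps <- lapply(1:3, function(i) mkMap(vals[[i]], subject = paste0("S", i),
                                        mask = masks[[i]]))
  loo <- betweenSubjectLoo(maps)
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    allValid <- masks[[others[1]]] & masks[[others[2]]]
    mm <- (vals[[others[1]]] + vals[[others[2]]]) / 2
    joint <- allValid & masks[[i]]
    x <- vals[[i]][joint]; y <- mm[joint]
    expect_equal(loo$r[i], cor(x, y), tolerance = 1e-12)
    expect_equal(loo$nTiles[i], sum(joint))
  }
  # permuting subjects permutes scores identically
  perm <- c(2, 3, 1)
  loo2 <- betweenSubjectLoo(maps[perm])
  expect_equal(loo2$r, loo$r[perm], tolerance = 1e-15)

  # a pure-noise outlier scores lowest against the structured majority
  set.seed(10)
  structured <- matrix(rnorm(64), 8, 8)
  cohort <- lapply(1:5, function(i)
    mkMap(structured + 0.2 * matrix(rnorm(64), 8, 8),
          subject = paste0("S", i)))
  cohort[[5]] <- mkMap(matrix(rnorm(64), 8, 8), subject = "S5")
  looN <- betweenSubjectLoo(cohort)
  expect_equal(which.min(looN$z), 5L)

  expect_error(betweenSubjectLoo(maps[1:2]), class = "cgrid_config_error")
})

test_that("paired t-test matches a numerical-integration oracle", {
  expect_error(pairedTTest(c(1, 2, 3), c(1, 2, 3)),
               class = "cgrid_degenerate_error")
  res <- pairedTTest(c(2, 0), c(1, 1))  # differences (1, -1)
  expect_equal(res$t, 0)
  expect_equal(res$df, 1)
  expect_equal(res$p, 1)

  set.seed(14)
  a <- rnorm(20, 0.5); b <- rnorm(20)
  res <- pairedTTest(a, b)
  d <- a - b; n <- length(d)
  tOracle <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(res$t, tOracle, tolerance = 1e-8)
  expect_equal(res$df, n - 1)
  # two-sided p by quadrature over the t density (independent of pt)
  df <- n - 1
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  tail <- integrate(dens, abs(tOracle), Inf, rel.tol = 1e-10)$value
  expect_equal(res$p, 2 * tail, tolerance = 1e-6)
})
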