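#' @include cgrid-map.R
NULL

.R_CLAMP <- 1 - 1e-7

#' Fisher z-transform and its inverse
#'
#' `fisherZ` is `atanh` applied after clamping r to +/-(1 - 1e-7) (perfectly
#' correlated synthetic patterns would otherwise map to infinity);
#' `inverseFisherZ` is `tanh`, used to convert group-averaged similarity
#' z-scores back to correlations.
#'
#' @param r Pearson correlation(s).
#' @param z Fisher z score(s).
#' @return numeric vector.
#' @examples
#' round(inverseFisherZ(0.8), 2)   # 0.66
#' round(inverseFisherZ(0.97), 2)  # 0.75
#' @export
fisherZ <- function(r) atanh(pmax(-.R_CLAMP, pmin(.R_CLAMP, r)))

#' @rdname fisherZ
#' @export
inverseFisherZ <- function(z) tanh(z)

.similarityScore <- function(r, n, context = list()) {
  structure(list(r = r, z = fisherZ(r), nTiles = n, context = context),
            class = "similarityScore")
}

#' @export
print.similarityScore <- function(x, ...) {
  cat(sprintf("similarity: r = %.4f, z = %.4f over %d tiles\n",
              x$r, x$z, x$nTiles))
  if (length(x$context))
    cat("  ", paste(names(x$context), unlist(x$context), sep = "=",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

.pearsonMasked <- function(va, ma, vb, mb, context = list()) {
  if (!identical(dim(va), dim(vb)))
    cgridStop("maps must have identical shape", "cgrid_shape_error")
  joint <- ma & mb
  n <- sum(joint)
  if (n < 3L)
    cgridStop(sprintf("only %d tiles valid in both maps; need at least 3", n),
              "cgrid_degenerate_error")
  x <- va[joint]; y <- vb[joint]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    cgridStop("zero variance over the jointly valid tiles",
              "cgrid_degenerate_error")
  .similarityScore(stats::cor(x, y), n, context)
}

#' @rdname pearsonSimilarity
setMethod("pearsonSimilarity", signature("CgridMap", "CgridMap"),
  function(a, b, ...) {
    .pearsonMasked(a@values, a@mask, b@values, b@mask,
                   list(subject = a@subject, task = a@task,
                        comparison = paste(a@hemisphere, "vs", b@hemisphere)))
  })

#' @rdname pearsonSimilarity
setMethod("pearsonSimilarity", signature("RoiSlice", "RoiSlice"),
  function(a, b, ...) {
    .pearsonMasked(a@values, a@mask, b@values, b@mask,
                   list(subject = a@subject, task = a@task, roi = a@roi,
                        comparison = paste(a@hemisphere, "vs", b@hemisphere)))
  })

#' @rdname pearsonSimilarity
setMethod("pearsonSimilarity", signature("matrix", "matrix"),
  function(a, b, ...) {
    .pearsonMasked(a, is.finite(a), b, is.finite(b))
  })

# locate a map by metadata in a list of CgridMaps
.findMap <- function(maps, subject = NULL, hemisphere = NULL, task = NULL) {
  hit <- vapply(maps, function(m) {
    (is.null(subject) || m@subject == subject) &&
      (is.null(hemisphere) || m@hemisphere == hemisphere) &&
      (is.null(task) || m@task == task)
  }, logical(1))
  w <- which(hit)
  if (length(w) == 0L)
    cgridStop(sprintf("no map for subject=%s hemisphere=%s task=%s",
                      subject, hemisphere, task), "cgrid_missing_map_error")
  maps[[w[1]]]
}

#' Within-subject (left-right) similarity scores
#'
#' For the feet and tongue tasks the left- and right-hemisphere patterns are
#' correlated directly; for the hand tasks the contralateral patterns are
#' paired (left-hemisphere pattern of the hand_right task versus
#' right-hemisphere pattern of the hand_left task). Each comparison is done
#' per ROI (M1 and S1) on oriented maps, giving 6 Fisher z scores whose mean
#' is the subject's within-subject similarity.
#'
#' @param maps list of oriented [CgridMap-class] objects for one subject,
#'   covering tasks feet, tongue, hand_left, hand_right in both hemispheres.
#' @return list with `scores` (data.frame: task, roi, r, z, nTiles) and
#'   `aggregate` (mean z over the 6 scores).
#' @export
withinSubjectScores <- function(maps) {
  for (m in maps)
    if (!m@oriented)
      cgridStop("all maps must be oriented (see orientGrid)",
                "cgrid_config_error")
  pairs <- list(
    feet = c("feet", "feet"),
    tongue = c("tongue", "tongue"),
    hand = c("hand_right", "hand_left")  # left hemi of hand_right vs right hemi of hand_left
  )
  rows <- list()
  for (nm in names(pairs)) {
    lm <- .findMap(maps, hemisphere = "left", task = pairs[[nm]][1])
    rm_ <- .findMap(maps, hemisphere = "right", task = pairs[[nm]][2])
    lh <- roiHalves(lm); rh <- roiHalves(rm_)
    for (roi in c("M1", "S1")) {
      sc <- pearsonSimilarity(lh[[roi]], rh[[roi]])
      rows[[length(rows) + 1L]] <- data.frame(
        task = nm, roi = roi, r = sc$r, z = sc$z, nTiles = sc$nTiles)
    }
  }
  scores <- do.call(rbind, rows)
  list(scores = scores, aggregate = mean(scores$z))
}

#' Between-subject leave-one-out similarity
#'
#' Each subject's ROI pattern is correlated with the tile-wise mean pattern
#' of all other subjects. The mean uses only tiles valid in every
#' contributing subject; the correlation then uses the tiles valid in both
#' the held-out subject and that mean.
#'
#' @param maps list of oriented [CgridMap-class] objects, one per subject,
#'   all for the same task and hemisphere.
#' @param roi `"M1"`, `"S1"`, or `"full"` for the whole grid.
#' @return data.frame with one row per subject: subject, r, z, nTiles.
#' @export
betweenSubjectLoo <- function(maps, roi = "full") {
  if (length(maps) < 3L)
    cgridStop("leave-one-out needs at least 3 subjects", "cgrid_config_error")
  getVm <- function(m) {
    if (roi == "full") list(v = m@values, mk = m@mask, id = m@subject)
    else {
      s <- roiHalves(m)[[roi]]
      list(v = s@values, mk = s@mask, id = m@subject)
    }
  }
  parts <- lapply(maps, getVm)
  rows <- lapply(seq_along(parts), function(i) {
    others <- parts[-i]
    allValid <- Reduce(`&`, lapply(others, `[[`, "mk"))
    stack <- Reduce(`+`, lapply(others, function(p) {
      v <- p$v; v[!allValid] <- 0; v
    }))
    meanMap <- stack / length(others)
    meanMap[!allValid] <- NA_real_
    sc <- .pearsonMasked(parts[[i]]$v, parts[[i]]$mk, meanMap, allValid,
                         list(subject = parts[[i]]$id, roi = roi,
                              comparison = "leave-one-out"))
    data.frame(subject = parts[[i]]$id, r = sc$r, z = sc$z,
               nTiles = sc$nTiles)
  })
  do.call(rbind, rows)
}

#' Paired-samples t-test on per-subject similarity scores
#'
#' Two-sided paired t-test, `t = mean(d) / (sd(d)/sqrt(n))` with
#' `df = n - 1`, as used to compare similarity scores between normalization
#' schemes.
#'
#' @param a,b numeric vectors of equal length (one value per subject).
#' @return list with `t`, `df`, `p`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    cgridStop("paired test needs two equal-length vectors of length >= 2",
              "cgrid_config_error")
  d <- a - b
  if (stats::sd(d) == 0)
    cgridStop("differences have zero variance; t statistic undefined",
              "cgrid_degenerate_error")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}
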