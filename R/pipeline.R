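#' @include synthetic.R similarity.R smoothing.R
NULL

#' Build oriented grid maps for a whole cohort
#'
#' Per subject and hemisphere: extracts the five borders, builds the grid,
#' smooths each task field on the mesh, averages it into tiles and applies
#' the display orientation. This is the standard evaluation pipeline used by
#' the similarity reports.
#'
#' @param cohort a cohort from [makeCohort()].
#' @param N,M grid dimensions (default 28 x 84).
#' @param fwhm surface smoothing kernel in a.u. (default 6).
#' @param convention flattening convention passed to [orientGrid()].
#' @param griddefs optional nested list `griddefs[[subject]][[hemisphere]]`
#'   of prebuilt [CgridDefinition-class]s to reuse (e.g. for a scrambled
#'   control on the same meshes).
#' @return list with `maps` (flat list of oriented [CgridMap-class]s) and
#'   `griddefs`.
#' @export
cohortCgridMaps <- function(cohort, N = 28L, M = 84L, fwhm = 6,
                            convention = "caret", griddefs = NULL) {
  maps <- list()
  gds <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    gds[[sub$id]] <- list()
    for (h in c("left", "right")) {
      mesh <- sub$meshes[[h]]
      gd <- if (!is.null(griddefs)) griddefs[[sub$id]][[h]]
      else {
        borders <- extractSmxBorders(mesh, cohort$dialect)
        buildCgrid(mesh, borders, N = N, M = M)
      }
      gds[[sub$id]][[h]] <- gd
      for (task in names(sub$fields[[h]])) {
        field <- smoothVertexField(sub$fields[[h]][[task]], mesh, fwhm)
        map <- mapToGrid(field, gd, subject = sub$id, task = task,
                         fieldName = "beta")
        maps[[length(maps) + 1L]] <- orientGrid(map, convention)
      }
    }
  }
  list(maps = maps, griddefs = gds)
}

#' Within-subject similarity report for a cohort
#'
#' Runs [withinSubjectScores()] for every subject and aggregates: one mean
#' Fisher z per subject, plus the group mean and s.d. and the group-mean
#' correlation `tanh(mean z)`.
#'
#' @param maps flat list of oriented [CgridMap-class]s (all subjects).
#' @return list with `perSubject` (data.frame subject, z), `groupMeanZ`,
#'   `groupSdZ`, `groupMeanR`.
#' @export
withinSubjectReport <- function(maps) {
  subjects <- unique(vapply(maps, function(m) m@subject, character(1)))
  rows <- lapply(subjects, function(s) {
    sm <- Filter(function(m) m@subject == s, maps)
    data.frame(subject = s, z = withinSubjectScores(sm)$aggregate)
  })
  per <- do.call(rbind, rows)
  list(perSubject = per, groupMeanZ = mean(per$z), groupSdZ = stats::sd(per$z),
       groupMeanR = inverseFisherZ(mean(per$z)))
}

#' Between-subject leave-one-out report for a cohort
#'
#' For every task, hemisphere and ROI (M1, S1) the leave-one-out similarity
#' of each subject against the mean of the others is computed; the scores
#' are then averaged per subject over tasks and ROIs.
#'
#' @param maps flat list of oriented [CgridMap-class]s (all subjects).
#' @param tasks tasks to include (default: all present).
#' @return list with `scores` (data.frame task, hemisphere, roi, subject, r,
#'   z), `perSubject` (subject, z), `groupMeanZ`, `groupSdZ`, `groupMeanR`.
#' @export
betweenSubjectReport <- function(maps, tasks = NULL) {
  if (is.null(tasks))
    tasks <- unique(vapply(maps, function(m) m@task, character(1)))
  rows <- list()
  for (task in tasks) {
    for (h in c("left", "right")) {
      sel <- Filter(function(m) m@task == task && m@hemisphere == h, maps)
      if (length(sel) < 3L) next
      for (roi in c("M1", "S1")) {
        df <- betweenSubjectLoo(sel, roi = roi)
        df$task <- task; df$hemisphere <- h; df$roi <- roi
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  scores <- do.call(rbind, rows)
  agg <- stats::aggregate(z ~ subject, data = scores, FUN = mean)
  list(scores = scores, perSubject = agg, groupMeanZ = mean(agg$z),
       groupSdZ = stats::sd(agg$z), groupMeanR = inverseFisherZ(mean(agg$z)))
}
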