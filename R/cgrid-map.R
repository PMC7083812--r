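#' @include cgrid-build.R
NULL

#' @rdname nRows
setMethod("nRows", "CgridMap", function(x) nrow(x@values))

#' @rdname nRows
setMethod("nCols", "CgridMap", function(x) ncol(x@values))

#' @rdname hemisphere
setMethod("hemisphere", "CgridMap", function(x) x@hemisphere)

#' @rdname gridValues
setMethod("gridValues", "CgridMap", function(x) x@values)

#' @rdname gridValues
setMethod("gridMask", "CgridMap", function(x) x@mask)

#' @rdname gridValues
setMethod("gridValues", "RoiSlice", function(x) x@values)

#' @rdname gridValues
setMethod("gridMask", "RoiSlice", function(x) x@mask)

setMethod("show", "CgridMap", function(object) {
  cat(sprintf("CgridMap %d x %d [%s, %s hemisphere, task %s, field %s]\n",
              nrow(object@values), ncol(object@values), object@subject,
              object@hemisphere, object@task, object@field))
  cat(sprintf("  %d valid tiles (%.1f%%); %s\n", sum(object@mask),
              100 * mean(object@mask),
              if (object@oriented) "oriented (precentral left, dorsal top)"
              else "unoriented (flat-map x order)"))
})

setMethod("show", "RoiSlice", function(object) {
  cat(sprintf("RoiSlice %s: %d x %d, %d valid tiles [%s, %s, %s]\n",
              object@roi, nrow(object@values), ncol(object@values),
              sum(object@mask), object@subject, object@hemisphere,
              object@task))
})

#' Average a per-vertex field into grid tiles
#'
#' Each tile's value is the unweighted arithmetic mean of the field over its
#' member vertices, dropping missing values. A tile is valid only when it
#' contains at least one region-of-interest (precentral/postcentral) vertex
#' with a finite value; invalid tiles are `NA` and excluded from the
#' correlation analyses downstream. The returned matrix is in display space:
#' row 1 dorsal, columns in flat-map x order (use [orientGrid()] before
#' comparing hemispheres).
#'
#' @param field numeric vector, one value per mesh vertex (`NA` = missing).
#' @param griddef a [CgridDefinition-class].
#' @param subject,task,fieldName metadata strings stored on the map.
#' @return a [CgridMap-class].
#' @export
mapToGrid <- function(field, griddef, subject = "subject", task = "task",
                      fieldName = "field") {
  N <- griddef@nRows; M <- griddef@nCols
  if (length(field) != length(griddef@assignment))
    cgridStop(sprintf("field has %d values for %d mesh vertices",
                      length(field), length(griddef@assignment)),
              "cgrid_shape_error")
  ok <- !is.na(griddef@assignment) & is.finite(field)
  idx <- griddef@assignment[ok]
  nt <- N * M
  sums <- numeric(nt); cnts <- numeric(nt)
  if (length(idx)) {
    s <- rowsum(field[ok], idx)
    sums[as.integer(rownames(s))] <- s
    cnts <- tabulate(idx, nbins = nt)
  }
  smxCnt <- tabulate(griddef@assignment[ok & griddef@smxVertex], nbins = nt)
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  mask <- smxCnt > 0 & cnts > 0
  vals[!mask] <- NA_real_
  # construction space -> display space (dorsal top, x-ascending columns)
  vC <- matrix(vals, N, M, byrow = TRUE)
  mC <- matrix(mask, N, M, byrow = TRUE)
  vD <- vC[N:1, , drop = FALSE]
  mD <- mC[N:1, , drop = FALSE]
  if (griddef@xReversed) {
    vD <- vD[, M:1, drop = FALSE]
    mD <- mD[, M:1, drop = FALSE]
  }
  new("CgridMap", values = vD, mask = mD, subject = subject,
      hemisphere = griddef@hemisphere, task = task, field = fieldName,
      oriented = FALSE)
}

#' Apply the display orientation convention
#'
#' By convention grid maps are displayed and processed with the precentral
#' sulcus on the left and the postcentral sulcus on the right regardless of
#' hemisphere (dorsal at the top). Which hemisphere needs its column order
#' flipped depends on the flattening tool's handedness: under the `"caret"`
#' convention the right-hemisphere flat map is mirrored in x, so right maps
#' are flipped; `"flipped"` declares the opposite handedness.
#'
#' Orientation is idempotent: an already-oriented map is returned unchanged
#' unless `force = TRUE`, which applies the flip decision again.
#'
#' @param map a [CgridMap-class].
#' @param convention `"caret"` or `"flipped"`.
#' @param force re-apply the flip even if the map is already oriented.
#' @return the oriented [CgridMap-class].
#' @export
orientGrid <- function(map, convention = c("caret", "flipped"),
                       force = FALSE) {
  convention <- match.arg(convention)
  if (map@oriented && !force) return(map)
  if (!map@hemisphere %in% c("left", "right"))
    cgridStop(sprintf("unknown hemisphere tag '%s'", map@hemisphere),
              "cgrid_config_error")
  flipHemi <- if (convention == "caret") "right" else "left"
  if (map@hemisphere == flipHemi) {
    M <- ncol(map@values)
    map@values <- map@values[, M:1, drop = FALSE]
    map@mask <- map@mask[, M:1, drop = FALSE]
  }
  map@oriented <- TRUE
  map
}

#' Is a grid map in display orientation?
#' @param map a [CgridMap-class].
#' @export
isOriented <- function(map) map@oriented

#' Split an oriented map into its M1 and S1 halves
#'
#' The left half of an oriented grid (columns 1..M/2) is the precentral
#' gyrus (M1), the right half (columns M/2+1..M) the postcentral gyrus (S1).
#'
#' @param map an oriented [CgridMap-class].
#' @return list with [RoiSlice-class] elements `M1` and `S1`.
#' @export
roiHalves <- function(map) {
  if (!map@oriented)
    cgridStop("map must be oriented before slicing into M1/S1",
              "cgrid_config_error")
  M <- ncol(map@values)
  if (M %% 2L != 0L)
    cgridStop("M must be even to split into M1/S1 halves", "cgrid_config_error")
  half <- M / 2L
  mk <- function(roi, cols) new("RoiSlice", roi = roi,
                                values = map@values[, cols, drop = FALSE],
                                mask = map@mask[, cols, drop = FALSE],
                                subject = map@subject,
                                hemisphere = map@hemisphere, task = map@task)
  list(M1 = mk("M1", seq_len(half)), S1 = mk("S1", half + seq_len(half)))
}

#' Peak tile of a grid map
#'
#' @param map a [CgridMap-class] or [RoiSlice-class].
#' @return integer `c(row, col)` of the maximum valid tile.
#' @export
gridPeak <- function(map) {
  v <- gridValues(map)
  v[!gridMask(map)] <- -Inf
  if (all(!is.finite(v)))
    cgridStop("no valid tiles; cannot locate a peak", "cgrid_degenerate_error")
  w <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
  as.integer(w)
}

#' Write / read a grid map as CSV plus JSON sidecar
#'
#' The CSV holds the N x M value matrix with empty cells for invalid tiles;
#' `<path>.json` stores the metadata.
#'
#' @param map a [CgridMap-class].
#' @param path CSV output path.
#' @return `writeCgridMap`: the path, invisibly; `readCgridMap`: a
#'   [CgridMap-class].
#' @export
writeCgridMap <- function(map, path) {
  vals <- map@values
  utils::write.table(vals, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  meta <- list(subject = map@subject, hemisphere = map@hemisphere,
               task = map@task, field = map@field, oriented = map@oriented)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCgridMap
#' @export
readCgridMap <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                      na.strings = ""))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("CgridMap", values = vals, mask = !is.na(vals),
      subject = meta$subject, hemisphere = meta$hemisphere,
      task = meta$task, field = meta$field, oriented = meta$oriented)
}

#' Write / read a grid definition as JSON
#'
#' Stores the curves, the vertex-to-tile table and geometry metadata in a
#' versioned JSON schema.
#'
#' @param griddef a [CgridDefinition-class].
#' @param path JSON output path.
#' @export
writeCgridDefinition <- function(griddef, path) {
  obj <- list(
    schema = "cgrid-definition-v1",
    nRows = griddef@nRows, nCols = griddef@nCols,
    hemisphere = griddef@hemisphere,
    yRange = griddef@yRange, xReversed = griddef@xReversed,
    curveLengths = griddef@curveLengths,
    curves = lapply(griddef@curves, function(m)
      list(x = unname(m[, 1]), y = unname(m[, 2]))),
    assignment = griddef@assignment,
    smxVertex = griddef@smxVertex)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeCgridDefinition
#' @export
readCgridDefinition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "cgrid-definition-v1"))
    cgridStop(sprintf("'%s' is not a cgrid definition file", path),
              "cgrid_format_error")
  curves <- lapply(obj$curves, function(m)
    cbind(x = as.numeric(m$x), y = as.numeric(m$y)))
  new("CgridDefinition", nRows = as.integer(obj$nRows),
      nCols = as.integer(obj$nCols), curves = curves,
      assignment = as.integer(obj$assignment),
      smxVertex = as.logical(obj$smxVertex),
      yRange = as.numeric(obj$yRange), xReversed = as.logical(obj$xReversed),
      hemisphere = obj$hemisphere,
      curveLengths = as.numeric(obj$curveLengths))
}
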