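#' @include flatmesh.R dialect.R
NULL

#' Specification of a synthetic flat-map subject
#'
#' Describes a curved, band-shaped two-gyrus region (precentral +
#' postcentral) surrounded by the eight neighbor regions used by
#' sensorimotor border extraction, emulating the inter-subject anatomical
#' variability of real flat maps with a smooth low-order harmonic warp.
#'
#' Defaults approximate a real sensorimotor strip: a 60 x 120 a.u. band
#' (tiles of about 3 a.u.^2 at the default 28 x 84 grid), vertex spacing
#' 0.7 a.u. (about 6 vertices per tile), and a warp of 5 a.u. amplitude.
#'
#' @param seed integer RNG seed; the generator is deterministic given the
#'   spec.
#' @param bandWidth anteroposterior band width in a.u.
#' @param bandHeight dorsoventral band height in a.u.
#' @param margin width of the labeled neighbor margin, as a fraction of the
#'   band dimensions.
#' @param warpAmplitude amplitude of the harmonic warp in a.u. (0 = identity
#'   warp, straight band).
#' @param warpOrder number of harmonics in the warp.
#' @param resolution target edge length in a.u.
#' @param hemisphere `"left"` or `"right"`; right-hemisphere meshes are
#'   mirrored in x.
#' @param hotspots optional data.frame of planted activation hotspots with
#'   columns `s`, `t` (parametric centers in `[0,1]^2`; s anteroposterior,
#'   t dorsoventral with t = 1 dorsal), `amplitude`, `width` (parametric
#'   s.d.), and optionally `tag`.
#' @return a list of class `subjectSpec`.
#' @seealso [makeSubjectFlatmap()], [makeActivation()], [makeCohort()]
#' @export
subjectSpec <- function(seed = 1L, bandWidth = 60, bandHeight = 120,
                        margin = 0.12, warpAmplitude = 5, warpOrder = 3L,
                        resolution = 0.7, hemisphere = "left",
                        hotspots = NULL) {
  if (warpAmplitude < 0)
    cgridStop("warpAmplitude must be >= 0", "cgrid_config_error")
  if (resolution <= 0)
    cgridStop("resolution must be > 0", "cgrid_config_error")
  if (!is.null(hotspots)) {
    if (any(hotspots$s < 0 | hotspots$s > 1 | hotspots$t < 0 | hotspots$t > 1))
      cgridStop("hotspot centers must lie in [0,1]^2", "cgrid_config_error")
    if (any(hotspots$width <= 0))
      cgridStop("hotspot widths must be > 0", "cgrid_config_error")
  }
  structure(list(seed = as.integer(seed), bandWidth = bandWidth,
                 bandHeight = bandHeight, margin = margin,
                 warpAmplitude = warpAmplitude,
                 warpOrder = as.integer(warpOrder),
                 resolution = resolution, hemisphere = hemisphere,
                 hotspots = hotspots),
            class = "subjectSpec")
}

# draw the harmonic warp coefficients for one subject
.drawWarp <- function(spec) {
  K <- spec$warpOrder
  amp <- spec$warpAmplitude
  withSeed(spec$seed, list(
    ax = stats::runif(K, -1, 1) * amp / seq_len(K),   # band bending (x by t)
    phx = stats::runif(K, 0, 2 * pi),
    cx = stats::runif(K, -1, 1) * 0.3 * amp / seq_len(K),  # shear (x by s)
    psx = stats::runif(K, 0, 2 * pi),
    by = stats::runif(K, -1, 1) * 0.5 * amp / seq_len(K),  # y by s
    phy = stats::runif(K, 0, 2 * pi)
  ))
}

.applyWarp <- function(s, t, spec, warp) {
  K <- spec$warpOrder
  x <- s * spec$bandWidth
  y <- t * spec$bandHeight
  for (k in seq_len(K)) {
    x <- x + warp$ax[k] * sin(pi * k * t + warp$phx[k]) +
         warp$cx[k] * sin(pi * k * s + warp$psx[k])
    y <- y + warp$by[k] * sin(pi * k * s + warp$phy[k])
  }
  if (spec$hemisphere == "right") x <- -x
  cbind(x = x, y = y)
}

# parametric labeling: band interior split at the central sulcus (s = 0.5),
# margins carry the eight neighbor regions in anatomical position
.parametricLabels <- function(s, t, dialect) {
  lab <- character(length(s))
  ant <- s < 0
  lab[ant & t >= 2 / 3] <- dialect[["superior_frontal"]]
  lab[ant & t >= 1 / 3 & t < 2 / 3] <- dialect[["caudal_middle_frontal"]]
  lab[ant & t < 1 / 3] <- dialect[["pars_opercularis"]]
  post <- s > 1
  lab[post & t >= 0.5] <- dialect[["superior_parietal"]]
  lab[post & t < 0.5] <- dialect[["supramarginal"]]
  mid <- !ant & !post
  lab[mid & t > 1] <- dialect[["paracentral"]]
  lab[mid & t < 0] <- dialect[["insula"]]
  inband <- mid & t >= 0 & t <= 1
  lab[inband & s < 0.5] <- dialect[["precentral"]]
  lab[inband & s >= 0.5] <- dialect[["postcentral"]]
  lab
}

#' Generate a synthetic labeled flat map
#'
#' Triangulates a parametric rectangle, maps it through a smooth seeded
#' harmonic warp, and labels vertices so that the band interior is
#' precentral/postcentral and the margins carry the eight neighbor regions
#' in anatomically correct positions (frontal labels anterior, parietal
#' posterior, paracentral lobule dorsal, insula ventral). The true
#' parametric coordinates of every vertex are stored in the mesh metadata
#' for use by validation oracles.
#'
#' @param spec a [subjectSpec()].
#' @param dialect label dialect to stamp onto the vertices.
#' @return a [FlatMesh-class].
#' @examples
#' mesh <- makeSubjectFlatmap(subjectSpec(seed = 7, resolution = 2))
#' mesh
#' @export
makeSubjectFlatmap <- function(spec, dialect = labelDialect("prose")) {
  dialect <- labelDialect(dialect)
  m <- spec$margin
  nS <- max(4L, round(spec$bandWidth * (1 + 2 * m) / spec$resolution)) + 1L
  nT <- max(4L, round(spec$bandHeight * (1 + 2 * m) / spec$resolution)) + 1L
  sVals <- seq(-m, 1 + m, length.out = nS)
  tVals <- seq(-m, 1 + m, length.out = nT)
  s <- rep(sVals, times = nT)
  t <- rep(tVals, each = nS)
  warp <- .drawWarp(spec)
  xy <- .applyWarp(s, t, spec, warp)
  # triangulate each grid cell with a fixed diagonal (interior valence 6)
  i0 <- rep(seq_len(nS - 1L), times = nT - 1L) +
    rep((seq_len(nT - 1L) - 1L) * nS, each = nS - 1L)
  f1 <- cbind(i0, i0 + 1L, i0 + nS)
  f2 <- cbind(i0 + 1L, i0 + nS + 1L, i0 + nS)
  faces <- rbind(f1, f2)
  # self-intersection guard: all faces must keep a consistent orientation
  ax <- xy[faces[, 2], 1] - xy[faces[, 1], 1]
  ay <- xy[faces[, 2], 2] - xy[faces[, 1], 2]
  bx <- xy[faces[, 3], 1] - xy[faces[, 1], 1]
  by <- xy[faces[, 3], 2] - xy[faces[, 1], 2]
  area2 <- ax * by - ay * bx
  if (length(unique(sign(area2[area2 != 0]))) > 1L)
    cgridStop(paste("warp folds the band onto itself;",
                    "lower warpAmplitude or raise resolution"),
              "cgrid_generation_error")
  labels <- .parametricLabels(s, t, dialect)
  FlatMesh(xy, faces, labels, hemisphere = spec$hemisphere,
           metadata = list(parametric = cbind(s = s, t = t), spec = spec))
}

#' Canonical somatotopic hotspots for a movement task
#'
#' Feet activation sits at the dorsal end of the band (t = 0.90), hand
#' activation at about one third down the dorsoventral axis (t = 0.67), and
#' tongue activation ventrally (t = 0.15). Group-average hotspots lie mostly
#' within the central sulcus, so each body part gets a single Gaussian
#' centered on the sulcus (s = 0.5), spilling into both gyri. Hand tasks are
#' predominantly contralateral: the ipsilateral hemisphere receives a
#' quarter of the contralateral amplitude.
#'
#' @param task `"feet"`, `"tongue"`, `"hand_left"` or `"hand_right"`.
#' @param hemisphere hemisphere of the mesh the field is for.
#' @param shift optional numeric `c(ds, dt)` added to the centers
#'   (inter-subject positional jitter; centers are clipped to `[0.02, 0.98]`).
#' @return hotspot data.frame (s, t, amplitude, width, tag).
#' @export
taskHotspots <- function(task, hemisphere = "left", shift = c(0, 0)) {
  tPos <- switch(task,
                 feet = 0.90,
                 tongue = 0.15,
                 hand_left = , hand_right = 0.67,
                 cgridStop(sprintf("unknown task '%s'", task),
                           "cgrid_config_error"))
  scale <- 1
  if (task %in% c("hand_left", "hand_right")) {
    contra <- if (task == "hand_left") "right" else "left"
    scale <- if (hemisphere == contra) 1 else 0.25
  }
  part <- sub("_(left|right)$", "", task)
  data.frame(
    s = pmin(0.98, pmax(0.02, 0.5 + shift[1])),
    t = pmin(0.98, pmax(0.02, tPos + shift[2])),
    amplitude = scale,
    width = 0.08,
    tag = part)
}

#' Plant activation hotspots on a synthetic mesh
#'
#' Evaluates a sum of isotropic parametric Gaussians at each vertex's true
#' parametric location (known to the generator) and adds white noise.
#'
#' @param mesh a synthetic [FlatMesh-class] (with parametric metadata).
#' @param hotspots hotspot data.frame (see [taskHotspots()]) or a
#'   [subjectSpec()] carrying one; `NULL` gives an all-zero field.
#' @param noiseSd standard deviation of the additive white noise.
#' @param seed seed for the noise; defaults to the mesh spec's seed + 777.
#' @return numeric per-vertex field with attribute `name`.
#' @export
makeActivation <- function(mesh, hotspots = NULL, noiseSd = 0, seed = NULL) {
  par <- meshParametric(mesh)
  if (is.null(par))
    cgridStop("mesh carries no parametric ground truth; not a synthetic mesh",
              "cgrid_config_error")
  if (inherits(hotspots, "subjectSpec")) hotspots <- hotspots$hotspots
  field <- numeric(nrow(par))
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    for (i in seq_len(nrow(hotspots))) {
      d2 <- (par[, 1] - hotspots$s[i])^2 + (par[, 2] - hotspots$t[i])^2
      field <- field + hotspots$amplitude[i] *
        exp(-d2 / (2 * hotspots$width[i]^2))
    }
  }
  if (noiseSd > 0) {
    if (is.null(seed)) {
      sp <- mesh@metadata$spec
      seed <- if (is.null(sp)) 777L else sp$seed + 777L
    }
    field <- field + withSeed(seed, stats::rnorm(length(field), 0, noiseSd))
  }
  structure(field, name = "activation")
}

#' Generate a synthetic multi-subject cohort
#'
#' Emulates a multi-subject, four-task evaluation design: per subject a left
#' and a right hemisphere (the right generated as a mirrored, independently
#' warped copy) and four task fields (feet and tongue bilateral, hand fields
#' predominantly contralateral) at canonical somatotopic positions. All
#' randomness derives from `seed`.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param baseSpec base [subjectSpec()]; per-subject seeds and warp
#'   amplitudes are derived from it.
#' @param warpJitter multiplier on the warp amplitude; 0 makes all subjects
#'   share an identical (unwarped) band.
#' @param hotspotJitterSd s.d. of the per-subject parametric shift applied
#'   to each body part's hotspots (shared across hemispheres; 0 = canonical
#'   positions for everyone).
#' @param noiseSd white-noise s.d. of the activation fields.
#' @param seed cohort seed.
#' @param scramble replace every subject's hotspots by random positions
#'   (uniform in `[0.1, 0.9]^2`), destroying the shared somatotopy while
#'   keeping amplitudes and widths; used as a negative control.
#' @param reuseMeshes optional cohort previously generated with the same
#'   mesh parameters and seed whose meshes should be reused (fields are
#'   regenerated; useful for scrambled controls).
#' @return list of class `cgridCohort` with elements `subjects` (each:
#'   `id`, `meshes$left/right`, `fields$left/right$<task>`), `dialect`,
#'   `tasks`.
#' @export
makeCohort <- function(nSubjects, baseSpec = subjectSpec(), warpJitter = 1,
                       hotspotJitterSd = 0, noiseSd = 0.05, seed = 1L,
                       scramble = FALSE, reuseMeshes = NULL) {
  if (nSubjects < 3L)
    cgridStop("a cohort needs at least 3 subjects", "cgrid_config_error")
  tasks <- c("feet", "tongue", "hand_left", "hand_right")
  parts <- c("feet", "tongue", "hand")
  draws <- withSeed(seed, list(
    meshSeeds = matrix(sample.int(1e6L, 2L * nSubjects), nSubjects, 2L),
    shifts = array(stats::rnorm(nSubjects * length(parts) * 2L, 0,
                                max(hotspotJitterSd, 1e-12)),
                   dim = c(nSubjects, length(parts), 2L)),
    scrambleCenters = array(stats::runif(nSubjects * length(parts) * 2L,
                                         0.1, 0.9),
                            dim = c(nSubjects, length(parts), 2L)),
    noiseSeeds = array(sample.int(1e6L, nSubjects * 2L * length(tasks)),
                       dim = c(nSubjects, 2L, length(tasks)))
  ))
  if (hotspotJitterSd == 0) draws$shifts[] <- 0
  dialect <- labelDialect("prose")
  subjects <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    meshes <- list()
    fields <- list(left = list(), right = list())
    for (h in c("left", "right")) {
      hi <- if (h == "left") 1L else 2L
      sp <- baseSpec
      sp$seed <- draws$meshSeeds[i, hi]
      sp$warpAmplitude <- baseSpec$warpAmplitude * warpJitter
      sp$hemisphere <- h
      meshes[[h]] <- if (!is.null(reuseMeshes))
        reuseMeshes$subjects[[i]]$meshes[[h]]
      else makeSubjectFlatmap(sp, dialect)
      for (ti in seq_along(tasks)) {
        task <- tasks[ti]
        part <- sub("_(left|right)$", "", task)
        pi_ <- match(part, parts)
        hs <- taskHotspots(task, h, shift = draws$shifts[i, pi_, ])
        if (scramble) {
          hs$s <- draws$scrambleCenters[i, pi_, 1L]
          hs$t <- draws$scrambleCenters[i, pi_, 2L]
        }
        fields[[h]][[task]] <- makeActivation(
          meshes[[h]], hs, noiseSd = noiseSd,
          seed = draws$noiseSeeds[i, hi, ti])
      }
    }
    subjects[[i]] <- list(id = sprintf("S%02d", i), meshes = meshes,
                          fields = fields)
  }
  structure(list(subjects = subjects, dialect = dialect, tasks = tasks),
            class = "cgridCohort")
}
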