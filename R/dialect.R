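#' @include utils.R
NULL

.dialectRoles <- c("precentral", "postcentral", "pars_opercularis",
                   "caudal_middle_frontal", "superior_frontal",
                   "supramarginal", "superior_parietal",
                   "paracentral", "insula")

.builtinDialects <- list(
  # human-readable region names
  prose = c(
    precentral            = "Precentral gyrus",
    postcentral           = "Postcentral gyrus",
    pars_opercularis      = "Pars opercularis",
    caudal_middle_frontal = "Caudal middle frontal",
    superior_frontal      = "Superior frontal",
    supramarginal         = "SupraMarginal",
    superior_parietal     = "SuperiorParietal",
    paracentral           = "ParacentralLobule",
    insula                = "Insula"
  ),
  # FreeSurfer aparc (Desikan-Killiany) short names as found in .annot files
  aparc = c(
    precentral            = "precentral",
    postcentral           = "postcentral",
    pars_opercularis      = "parsopercularis",
    caudal_middle_frontal = "caudalmiddlefrontal",
    superior_frontal      = "superiorfrontal",
    supramarginal         = "supramarginal",
    superior_parietal     = "superiorparietal",
    paracentral           = "paracentral",
    insula                = "insula"
  )
)

#' Label dialects: mapping canonical region roles to on-disk label strings
#'
#' Atlas parcellations name the same regions differently across sources
#' (human-readable names versus FreeSurfer aparc short names). A dialect maps
#' the nine canonical roles used by sensorimotor border extraction
#' (precentral, postcentral, pars_opercularis, caudal_middle_frontal,
#' superior_frontal, supramarginal, superior_parietal, paracentral, insula)
#' to the literal strings of a given annotation source. Matching is
#' exact-string.
#'
#' @param dialect either the name of a built-in dialect (`"prose"` or
#'   `"aparc"`) or a named character vector supplying all nine roles.
#' @return a named character vector (roles to label strings).
#' @examples
#' labelDialect("aparc")[["precentral"]]
#' @export
labelDialect <- function(dialect = "prose") {
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect))) {
    if (!dialect %in% names(.builtinDialects))
      cgridStop(sprintf("unknown built-in dialect '%s'", dialect),
                "cgrid_config_error")
    return(.builtinDialects[[dialect]])
  }
  d <- dialect
  missing <- setdiff(.dialectRoles, names(d))
  if (length(missing))
    cgridStop(paste0("dialect lacks role(s): ", paste(missing, collapse = ", ")),
              "cgrid_label_error")
  if (anyDuplicated(d))
    cgridStop("dialect label strings must be unique", "cgrid_label_error")
  d[.dialectRoles]
}

#' @rdname labelDialect
#' @export
dialectRoles <- function() .dialectRoles
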