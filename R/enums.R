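#' Controlled vocabularies of the corpus data model
#'
#' Every comparison in a corpus is annotated with five categorical moderators.
#' The levels below are the canonical spellings used throughout the package;
#' [canonicalize_level()] maps common variants onto them.
#'
#' @format A named list of character vectors with elements `design_type`,
#'   `biome`, `pressure`, `organism` and `scale`.
#' @export
ordimeta_levels <- list(
  design_type = c("field observation", "field manipulation", "experimental"),
  biome       = c("terrestrial", "freshwater", "marine"),
  pressure    = c("habitat change", "pollution", "resource exploitation",
                  "invasive species", "climate change"),
  organism    = c("invertebrates", "microbes", "plants", "fungi", "fish",
                  "birds", "reptiles and amphibians", "mammals", "others"),
  scale       = c("point/microhabitat", "plot", "local", "regional",
                  "continental/global"),
  group       = c("reference", "impacted")
)

# synonym -> canonical level, applied after lower-casing and trimming.
# "land-use change" and "habitat change" are used interchangeably in the
# literature this data model serves; a few other frequent variants included.
.level_synonyms <- c(
  "land-use change"        = "habitat change",
  "land use change"        = "habitat change",
  "habitat loss"           = "habitat change",
  "exploitation"           = "resource exploitation",
  "overexploitation"       = "resource exploitation",
  "invasion"               = "invasive species",
  "invasive"               = "invasive species",
  "warming"                = "climate change",
  "reptiles & amphibians"  = "reptiles and amphibians",
  "herpetofauna"           = "reptiles and amphibians",
  "amphibians and reptiles" = "reptiles and amphibians",
  "micro-organisms"        = "microbes",
  "microorganisms"         = "microbes",
  "observational"          = "field observation",
  "observation"            = "field observation",
  "manipulation"           = "field manipulation",
  "experiment"             = "experimental",
  "control"                = "reference",
  "impact"                 = "impacted",
  "point"                  = "point/microhabitat",
  "microhabitat"           = "point/microhabitat",
  "continental"            = "continental/global",
  "global"                 = "continental/global"
)

#' Canonicalize a categorical label
#'
#' Case-insensitive, whitespace-trimmed matching of a label against the
#' canonical levels of one of the corpus vocabularies, with a small synonym
#' table (e.g. `"land-use change"` maps to `"habitat change"`).
#'
#' @param x character vector of raw labels.
#' @param field one of `"design_type"`, `"biome"`, `"pressure"`, `"organism"`,
#'   `"scale"`, `"group"`.
#' @return character vector of canonical levels.
#' @examples
#' canonicalize_level("Pollution ", "pressure")
#' canonicalize_level("Land-Use Change", "pressure")
#' @export
canonicalize_level <- function(x, field) {
  field <- match.arg(field, names(ordimeta_levels))
  levels <- ordimeta_levels[[field]]
  raw <- tolower(trimws(as.character(x)))
  raw[raw %in% names(.level_synonyms)] <-
    .level_synonyms[raw[raw %in% names(.level_synonyms)]]
  bad <- !is.na(raw) & !(raw %in% levels)
  if (any(bad)) {
    stop(sprintf("unknown %s label(s): %s (row %s)", field,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  raw
}

#' Spatial-scale category from geographic extent
#'
#' Classifies the geographic extent of the reference sites (distance in metres
#' between the two furthest reference sites) into the five spatial-scale
#' categories. Bins are half-open `[lo, hi)`: `[0, 10)` point/microhabitat,
#' `[10, 1e3)` plot, `[1e3, 1e5)` local, `[1e5, 1e6)` regional and
#' `[1e6, Inf)` continental/global.
#'
#' @param extent_m numeric vector of extents in metres, all `>= 0`.
#' @return character vector of scale categories.
#' @examples
#' scale_category(c(0, 10, 1500000))
#' @export
scale_category <- function(extent_m) {
  if (!is.numeric(extent_m) || any(!is.finite(extent_m)))
    stop("extent_m must be finite numeric", call. = FALSE)
  if (any(extent_m < 0))
    stop("extent_m must be non-negative", call. = FALSE)
  breaks <- c(0, 10, 1e3, 1e5, 1e6, Inf)
  ordimeta_levels$scale[findInterval(extent_m, breaks)]
}
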