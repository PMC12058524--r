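#' Assemble a meta-analysis dataset of control-impact comparisons
#'
#' The central container of the package. A `meta_dataset` bundles one row of
#' study-level metadata per comparison (`records`), the 2D ordination
#' coordinates of every extracted community (`points`, long format, one row
#' per point) and, optionally, the mean local taxonomic richness of the
#' reference and impacted groups (`richness`).
#'
#' @param records data.frame with columns `comparison_id`, `publication_id`,
#'   `design_type`, `biome`, `pressure`, `organism`, `scale`. One row per
#'   comparison; `comparison_id` must be unique, `publication_id` non-empty.
#' @param points data.frame with columns `comparison_id`, `group`
#'   (`"reference"` or `"impacted"`), `axis1`, `axis2`. Coordinates are in the
#'   (unitless) scale of the source ordination and must be finite.
#' @param richness optional data.frame with columns `comparison_id`,
#'   `alpha_ref_mean`, `alpha_imp_mean` (mean local richness per group).
#' @param provenance free-text provenance string (source file, generator seed).
#' @return An object of class `meta_dataset`.
#' @seealso [read_comparisons()], [validate_dataset()], [compute_effects()]
#' @export
meta_dataset <- function(records, points, richness = NULL, provenance = "") {
  records <- as.data.frame(records)
  points <- as.data.frame(points)
  req_rec <- c("comparison_id", "publication_id", "design_type", "biome",
               "pressure", "organism", "scale")
  miss <- setdiff(req_rec, names(records))
  if (length(miss))
    stop("records is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  req_pts <- c("comparison_id", "group", "axis1", "axis2")
  miss <- setdiff(req_pts, names(points))
  if (length(miss))
    stop("points is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # an empty dataset is representable (e.g. after total publication-bias
  # censoring); model fitting rejects it downstream
  records$comparison_id <- as.character(records$comparison_id)
  records$publication_id <- as.character(records$publication_id)
  if (anyDuplicated(records$comparison_id))
    stop("duplicate comparison_id in records: ",
         paste(unique(records$comparison_id[duplicated(records$comparison_id)]),
               collapse = ", "), call. = FALSE)
  if (any(is.na(records$publication_id) | records$publication_id == ""))
    stop("publication_id must be non-empty for every record", call. = FALSE)
  for (f in c("design_type", "biome", "pressure", "organism", "scale"))
    records[[f]] <- canonicalize_level(records[[f]], f)
  points$comparison_id <- as.character(points$comparison_id)
  points$group <- canonicalize_level(points$group, "group")
  points$axis1 <- as.numeric(points$axis1)
  points$axis2 <- as.numeric(points$axis2)
  if (any(!is.finite(points$axis1)) || any(!is.finite(points$axis2)))
    stop("point coordinates must be finite", call. = FALSE)
  orphan <- setdiff(points$comparison_id, records$comparison_id)
  if (length(orphan))
    stop("points refer to unknown comparison_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  if (!is.null(richness)) {
    richness <- as.data.frame(richness)
    req_rich <- c("comparison_id", "alpha_ref_mean", "alpha_imp_mean")
    miss <- setdiff(req_rich, names(richness))
    if (length(miss))
      stop("richness is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    richness$comparison_id <- as.character(richness$comparison_id)
    if (anyDuplicated(richness$comparison_id))
      stop("duplicate comparison_id in richness table", call. = FALSE)
    orphan <- setdiff(richness$comparison_id, records$comparison_id)
    if (length(orphan))
      stop("richness refers to unknown comparison_id: ",
           paste(orphan, collapse = ", "), call. = FALSE)
  }
  records <- records[, req_rec]; rownames(records) <- NULL
  points <- points[, req_pts]; rownames(points) <- NULL
  if (!is.null(richness)) {
    richness <- richness[, c("comparison_id", "alpha_ref_mean",
                             "alpha_imp_mean")]
    rownames(richness) <- NULL
  }
  structure(
    list(records = records, points = points, richness = richness,
         provenance = as.character(provenance)),
    class = "meta_dataset"
  )
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("meta_dataset:", nrow(x$records), "comparisons,",
      length(unique(x$records$publication_id)), "publications,",
      nrow(x$points), "points\n")
  if (!is.null(x$richness))
    cat("  local-richness pairs for", nrow(x$richness), "comparisons\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Per-comparison eligibility report
#'
#' Pure validation pass over a dataset: reports, for every comparison, the
#' group sizes and whether it is eligible for the distance-based effect sizes
#' (at least two points per group) and for the local-diversity effect size
#' (richness pair present with both means strictly positive). Reports, never
#' throws, and never mutates its input.
#'
#' @param dataset a [meta_dataset()].
#' @return data.frame with columns `comparison_id`, `n_reference`,
#'   `n_impacted`, `eligible_distance` (homogeneity/shift), `eligible_richness`
#'   and `reason` (empty string when fully eligible).
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  ids <- dataset$records$comparison_id
  fid <- factor(dataset$points$comparison_id, levels = ids)
  n_ref <- as.integer(table(fid[dataset$points$group == "reference"]))
  n_imp <- as.integer(table(fid[dataset$points$group == "impacted"]))
  eligible_distance <- n_ref >= 2L & n_imp >= 2L
  eligible_richness <- rep(FALSE, length(ids))
  if (!is.null(dataset$richness)) {
    m <- match(ids, dataset$richness$comparison_id)
    has <- !is.na(m)
    pos <- has
    pos[has] <- is.finite(dataset$richness$alpha_ref_mean[m[has]]) &
      is.finite(dataset$richness$alpha_imp_mean[m[has]]) &
      dataset$richness$alpha_ref_mean[m[has]] > 0 &
      dataset$richness$alpha_imp_mean[m[has]] > 0
    eligible_richness <- pos
  }
  reason <- character(length(ids))
  reason[!eligible_distance] <- "fewer than 2 points in a group"
  no_rich <- !eligible_richness
  reason[no_rich] <- ifelse(
    nzchar(reason[no_rich]),
    paste0(reason[no_rich], "; no valid richness pair"),
    "no valid richness pair")
  data.frame(comparison_id = ids, n_reference = n_ref, n_impacted = n_imp,
             eligible_distance = eligible_distance,
             eligible_richness = eligible_richness,
             reason = reason, stringsAsFactors = FALSE)
}
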