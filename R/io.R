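#' Read a comparisons table (and optional richness table) from CSV
#'
#' The interchange format is long: one row per extracted point, with the
#' study-level metadata repeated on every row. Required columns:
#' `comparison_id`, `publication_id`, `design_type`, `biome`, `pressure`,
#' `organism`, `scale`, `group`, `axis1`, `axis2`. Categorical labels are
#' canonicalized case-insensitively (see [canonicalize_level()]). Metadata
#' must be constant within a `comparison_id`; conflicting rows are an
#' integrity error.
#'
#' @param path path to the comparisons CSV (UTF-8, comma separated, `.`
#'   decimal).
#' @param richness_path optional path to a richness CSV with columns
#'   `comparison_id`, `alpha_ref_mean`, `alpha_imp_mean`.
#' @return a [meta_dataset()].
#' @export
read_comparisons <- function(path, richness_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("comparison_id", "publication_id", "design_type", "biome",
           "pressure", "organism", "scale", "group", "axis1", "axis2")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("comparisons file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw$comparison_id <- as.character(raw$comparison_id)
  meta_cols <- c("publication_id", "design_type", "biome", "pressure",
                 "organism", "scale")
  for (col in meta_cols) {
    n_distinct <- tapply(raw[[col]], raw$comparison_id,
                         function(v) length(unique(v)))
    if (any(n_distinct > 1L))
      stop("integrity error: column '", col,
           "' is not constant within comparison_id ",
           paste(names(n_distinct)[n_distinct > 1L], collapse = ", "),
           call. = FALSE)
  }
  first <- raw[!duplicated(raw$comparison_id), c("comparison_id", meta_cols)]
  richness <- NULL
  if (!is.null(richness_path)) {
    if (!file.exists(richness_path))
      stop("file not found: ", richness_path, call. = FALSE)
    richness <- utils::read.csv(richness_path, stringsAsFactors = FALSE)
  }
  meta_dataset(records = first,
               points = raw[, c("comparison_id", "group", "axis1", "axis2")],
               richness = richness,
               provenance = paste0("read from ", path))
}

#' Write a dataset to the CSV interchange format
#'
#' Inverse of [read_comparisons()]: writes the long-format comparisons table
#' (deterministic column order, one row per point) and, when the dataset
#' carries richness pairs, a companion richness table. Reading the files back
#' reproduces the dataset exactly (strings bit-identically, coordinates to
#' full printed precision).
#'
#' @param dataset a [meta_dataset()].
#' @param path output path for the comparisons CSV.
#' @param richness_path output path for the richness CSV; defaults to
#'   `<path without extension>_richness.csv` when the dataset has richness.
#' @return invisibly, the path(s) written.
#' @export
write_comparisons <- function(dataset, path, richness_path = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  m <- match(dataset$points$comparison_id, dataset$records$comparison_id)
  out <- data.frame(
    comparison_id = dataset$points$comparison_id,
    publication_id = dataset$records$publication_id[m],
    design_type = dataset$records$design_type[m],
    biome = dataset$records$biome[m],
    pressure = dataset$records$pressure[m],
    organism = dataset$records$organism[m],
    scale = dataset$records$scale[m],
    group = dataset$points$group,
    axis1 = dataset$points$axis1,
    axis2 = dataset$points$axis2,
    stringsAsFactors = FALSE
  )
  ord <- order(match(out$comparison_id, dataset$records$comparison_id))
  utils::write.csv(out[ord, ], path, row.names = FALSE, quote = TRUE)
  paths <- path
  if (!is.null(dataset$richness)) {
    if (is.null(richness_path))
      richness_path <- paste0(sub("\\.csv$", "", path), "_richness.csv")
    utils::write.csv(dataset$richness, richness_path, row.names = FALSE,
                     quote = TRUE)
    paths <- c(paths, richness_path)
  }
  invisible(paths)
}

#' Write a per-comparison effect-size table to CSV
#'
#' @param effects data.frame as returned by [compute_effects()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
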