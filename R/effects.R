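#' Mean pairwise distances within and between groups
#'
#' From labelled 2D coordinates, computes the four distance summaries that the
#' log-response-ratio effect sizes are built on: the mean Euclidean distance
#' among reference points (`D_R_bar`), among impacted points (`D_I_bar`),
#' between the two groups (`D_B_bar`, all cross pairs), and the pooled
#' within-group mean (`D_W_bar`) — the mean over *all* within-group pairs,
#' i.e. the pair-count-weighted pooling of the two group means.
#'
#' @param points numeric matrix (or data.frame) with two columns, one row per
#'   community.
#' @param labels character vector parallel to `points`, values `"reference"`
#'   or `"impacted"`.
#' @param check if `TRUE` (default), error when a group has fewer than two
#'   points or is fully coincident (within mean 0); if `FALSE`, return the
#'   summaries with `NA`/zero entries where undefined, for callers that handle
#'   eligibility themselves.
#' @return list of class `distance_summary` with components `D_R_bar`,
#'   `D_I_bar`, `D_B_bar`, `D_W_bar`, group sizes `n_reference`/`n_impacted`
#'   and pair counts `n_pairs_reference`/`n_pairs_impacted`/`n_pairs_between`.
#' @examples
#' s <- pairwise_group_means(rbind(c(0, 0), c(0, 2), c(1, 0), c(1, 1)),
#'                           c("reference", "reference", "impacted", "impacted"))
#' s$D_B_bar  # (1 + sqrt(2) + sqrt(5) + sqrt(2)) / 4
#' @export
pairwise_group_means <- function(points, labels, check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("points must have exactly two coordinate columns", call. = FALSE)
  if (nrow(points) != length(labels))
    stop("points and labels lengths differ", call. = FALSE)
  if (any(!is.finite(points)))
    stop("coordinates must be finite", call. = FALSE)
  labels <- canonicalize_level(labels, "group")
  ref <- points[labels == "reference", , drop = FALSE]
  imp <- points[labels == "impacted", , drop = FALSE]
  n_r <- nrow(ref); n_i <- nrow(imp)
  if (check && (n_r < 2L || n_i < 2L))
    stop("each group needs at least 2 points (reference: ", n_r,
         ", impacted: ", n_i, ")", call. = FALSE)

  mean_within <- function(x) {
    if (nrow(x) < 2L) return(NA_real_)
    mean(stats::dist(x))
  }
  d_r <- mean_within(ref)
  d_i <- mean_within(imp)
  if (check && ((is.finite(d_r) && d_r == 0) || (is.finite(d_i) && d_i == 0)))
    stop("a group is fully coincident: mean within-group distance is zero",
         call. = FALSE)
  # cross-group distances
  if (n_r >= 1L && n_i >= 1L) {
    cross <- sqrt(outer(ref[, 1], imp[, 1], "-")^2 +
                  outer(ref[, 2], imp[, 2], "-")^2)
    d_b <- mean(cross)
  } else d_b <- NA_real_
  p_r <- if (n_r >= 2L) n_r * (n_r - 1L) / 2 else 0
  p_i <- if (n_i >= 2L) n_i * (n_i - 1L) / 2 else 0
  d_w <- if (p_r + p_i > 0)
    (ifelse(p_r > 0, d_r * p_r, 0) + ifelse(p_i > 0, d_i * p_i, 0)) / (p_r + p_i)
  else NA_real_
  structure(list(D_R_bar = d_r, D_I_bar = d_i, D_B_bar = d_b, D_W_bar = d_w,
                 n_reference = n_r, n_impacted = n_i,
                 n_pairs_reference = p_r, n_pairs_impacted = p_i,
                 n_pairs_between = n_r * n_i),
            class = "distance_summary")
}

#' Log response ratio of community homogeneity
#'
#' `-ln(D_I_bar / D_R_bar)`: the log ratio of the mean pairwise distance among
#' impacted communities to that among reference communities, sign-flipped so
#' that positive values mean the impacted communities are more *homogeneous*
#' (biotic homogenization) and negative values mean biotic differentiation.
#'
#' @param s a `distance_summary` from [pairwise_group_means()].
#' @return scalar effect size (dimensionless).
#' @export
lrr_homogeneity <- function(s) {
  stopifnot(inherits(s, "distance_summary"))
  if (!is.finite(s$D_I_bar) || !is.finite(s$D_R_bar) ||
      s$D_I_bar <= 0 || s$D_R_bar <= 0)
    stop("LRR homogeneity undefined: both within-group mean distances must be positive",
         call. = FALSE)
  -log(s$D_I_bar / s$D_R_bar)
}

#' Log response ratio of compositional shift
#'
#' `ln(D_B_bar / D_W_bar)`: the log ratio of the mean between-group distance
#' to the pooled mean within-group distance. Positive values mean the impacted
#' communities have shifted away from the reference communities relative to
#' their internal spread. Invariant to swapping the group labels.
#'
#' @inheritParams lrr_homogeneity
#' @return scalar effect size (dimensionless).
#' @export
lrr_shift <- function(s) {
  stopifnot(inherits(s, "distance_summary"))
  if (!is.finite(s$D_B_bar) || !is.finite(s$D_W_bar) ||
      s$D_B_bar <= 0 || s$D_W_bar <= 0)
    stop("LRR shift undefined: between and within mean distances must be positive",
         call. = FALSE)
  log(s$D_B_bar / s$D_W_bar)
}

#' Log response ratio of local diversity
#'
#' `ln(alpha_I_bar / alpha_R_bar)`: log ratio of the mean local taxonomic
#' richness of the impacted communities to that of the reference communities.
#'
#' @param alpha_ref_mean mean local richness of the reference group (`> 0`).
#' @param alpha_imp_mean mean local richness of the impacted group (`> 0`).
#' @return scalar effect size (dimensionless).
#' @export
lrr_local_diversity <- function(alpha_ref_mean, alpha_imp_mean) {
  if (!is.finite(alpha_ref_mean) || !is.finite(alpha_imp_mean) ||
      alpha_ref_mean <= 0 || alpha_imp_mean <= 0)
    stop("LRR local diversity undefined: both mean richness values must be positive",
         call. = FALSE)
  log(alpha_imp_mean / alpha_ref_mean)
}

#' Per-comparison effect sizes for a whole dataset
#'
#' Applies the three log-response-ratio effect sizes to every comparison of a
#' dataset. Ineligible comparisons are kept in the output with `NA` effect
#' sizes and a machine-readable reason code; eligibility is assessed per
#' effect size, so e.g. a comparison whose impacted group is fully coincident
#' still gets an `lrr_shift` if the pooled within mean is positive.
#'
#' @param dataset a [meta_dataset()].
#' @return data.frame with one row per comparison: `comparison_id`,
#'   `lrr_homogeneity`, `lrr_shift`, `lrr_local_diversity`, `n_reference`,
#'   `n_impacted`, `n_points` and `reason` (empty when all three computed).
#' @export
compute_effects <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  ids <- dataset$records$comparison_id
  if (length(ids) == 0L)
    return(data.frame(comparison_id = character(0),
                      lrr_homogeneity = numeric(0), lrr_shift = numeric(0),
                      lrr_local_diversity = numeric(0),
                      n_reference = integer(0), n_impacted = integer(0),
                      n_points = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(comparison_id = ids,
                    lrr_homogeneity = NA_real_, lrr_shift = NA_real_,
                    lrr_local_diversity = NA_real_,
                    n_reference = 0L, n_impacted = 0L, n_points = 0L,
                    reason = "", stringsAsFactors = FALSE)
  rich <- dataset$richness
  idx <- split(seq_len(nrow(dataset$points)),
               factor(dataset$points$comparison_id, levels = ids))
  pts_all <- cbind(dataset$points$axis1, dataset$points$axis2)
  for (i in seq_along(ids)) {
    sel <- idx[[i]]
    pts <- pts_all[sel, , drop = FALSE]
    lab <- dataset$points$group[sel]
    reasons <- character(0)
    s <- pairwise_group_means(pts, lab, check = FALSE)
    out$n_reference[i] <- s$n_reference
    out$n_impacted[i] <- s$n_impacted
    out$n_points[i] <- s$n_reference + s$n_impacted
    if (s$n_reference < 2L || s$n_impacted < 2L) {
      reasons <- c(reasons, "fewer than 2 points in a group")
    } else {
      if (is.finite(s$D_I_bar) && is.finite(s$D_R_bar) &&
          s$D_I_bar > 0 && s$D_R_bar > 0)
        out$lrr_homogeneity[i] <- -log(s$D_I_bar / s$D_R_bar)
      else reasons <- c(reasons, "zero within-group distance (homogeneity)")
    }
    if (is.finite(s$D_B_bar) && is.finite(s$D_W_bar) &&
        s$D_B_bar > 0 && s$D_W_bar > 0)
      out$lrr_shift[i] <- log(s$D_B_bar / s$D_W_bar)
    else reasons <- c(reasons, "shift undefined (zero or missing distances)")
    if (!is.null(rich)) {
      j <- match(ids[i], rich$comparison_id)
      if (!is.na(j) && is.finite(rich$alpha_ref_mean[j]) &&
          is.finite(rich$alpha_imp_mean[j]) &&
          rich$alpha_ref_mean[j] > 0 && rich$alpha_imp_mean[j] > 0) {
        out$lrr_local_diversity[i] <-
          log(rich$alpha_imp_mean[j] / rich$alpha_ref_mean[j])
      } else if (!is.na(j)) {
        reasons <- c(reasons, "non-positive mean richness")
      }
    }
    out$reason[i] <- paste(reasons, collapse = "; ")
  }
  out
}

#' Spatial analogues of the two distance-based effect sizes
#'
#' Applies the homogeneity and shift log response ratios to inter-site
#' *geographic* distances instead of community distances: `spatial_homogeneity`
#' compares the spatial spread of the impacted site layout to the reference
#' layout, and `spatial_shift` compares between-layout to within-layout
#' distances.
#'
#' @param site_coords matrix/data.frame with two columns: planar x/y in a
#'   common projected unit when `metric = "euclidean"`, or longitude/latitude
#'   in decimal degrees when `metric = "haversine"`.
#' @param labels group labels (`"reference"`/`"impacted"`) per site.
#' @param metric `"euclidean"` (planar) or `"haversine"` (great-circle, on a
#'   sphere of radius 6,371,000 m).
#' @return named numeric vector `c(spatial_homogeneity=, spatial_shift=)`.
#' @export
spatial_lrrs <- function(site_coords, labels,
                         metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  site_coords <- as.matrix(site_coords)
  if (metric == "haversine") {
    # embed is not possible for great-circle distances; compute the four mean
    # distances directly from the haversine distance matrix
    labels <- canonicalize_level(labels, "group")
    n <- nrow(site_coords)
    if (n != length(labels)) stop("coords and labels lengths differ", call. = FALSE)
    d <- .haversine_matrix(site_coords)
    ref <- which(labels == "reference"); imp <- which(labels == "impacted")
    if (length(ref) < 2L || length(imp) < 2L)
      stop("each group needs at least 2 sites", call. = FALSE)
    d_r <- mean(d[ref, ref][upper.tri(diag(length(ref)))])
    d_i <- mean(d[imp, imp][upper.tri(diag(length(imp)))])
    d_b <- mean(d[ref, imp])
    p_r <- choose(length(ref), 2); p_i <- choose(length(imp), 2)
    d_w <- (d_r * p_r + d_i * p_i) / (p_r + p_i)
    if (d_r <= 0 || d_i <= 0 || d_b <= 0 || d_w <= 0)
      stop("degenerate site layout: zero mean distance", call. = FALSE)
    return(c(spatial_homogeneity = -log(d_i / d_r),
             spatial_shift = log(d_b / d_w)))
  }
  s <- pairwise_group_means(site_coords, labels)
  c(spatial_homogeneity = lrr_homogeneity(s), spatial_shift = lrr_shift(s))
}

# great-circle distance matrix in metres; coords = (lon, lat) degrees
.haversine_matrix <- function(coords) {
  lon <- coords[, 1] * pi / 180
  lat <- coords[, 2] * pi / 180
  n <- length(lon)
  dlat <- outer(lat, lat, "-") / 2
  dlon <- outer(lon, lon, "-") / 2
  a <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  6371000 * 2 * asin(sqrt(a))
}
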