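#' Ground-truth parameters for one simulated comparison
#'
#' Bundles the generative parameters of a single control-impact comparison:
#' reference communities are drawn around a latent centroid with unit spread;
#' impacted communities around a centroid displaced by `shift_delta`, with
#' spread multiplied by `dispersion_ratio`, in `latent_dim` latent dimensions.
#' Taxa are retained in the impacted group with probability `richness_ratio`,
#' so the expected impacted richness is about `richness_ratio` times the
#' reference richness.
#'
#' @param dispersion_ratio impacted/reference latent spread ratio, `> 0`.
#'   Values below 1 produce biotic homogenization (positive LRR homogeneity).
#' @param shift_delta latent centroid displacement, `>= 0`, in units of the
#'   reference spread.
#' @param richness_ratio per-taxon retention probability in the impacted
#'   group, in `(0, 1]`.
#' @param n_ref,n_imp number of reference / impacted communities (`>= 2`).
#' @param latent_dim latent dimensionality (`>= 2`). 2 means the 2D ordination
#'   can represent the communities exactly.
#' @param n_taxa number of taxa in the regional pool.
#' @param base_abundance expected abundance of a taxon at the latent origin;
#'   high values make detection near-perfect.
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(dispersion_ratio = 1, shift_delta = 0,
                      richness_ratio = 1, n_ref = 10L, n_imp = 10L,
                      latent_dim = 2L, n_taxa = 60L, base_abundance = 20) {
  if (dispersion_ratio <= 0) stop("dispersion_ratio must be > 0", call. = FALSE)
  if (shift_delta < 0) stop("shift_delta must be >= 0", call. = FALSE)
  if (richness_ratio <= 0 || richness_ratio > 1)
    stop("richness_ratio must be in (0, 1]", call. = FALSE)
  if (n_ref < 2L || n_imp < 2L)
    stop("n_ref and n_imp must be >= 2", call. = FALSE)
  if (latent_dim < 2L) stop("latent_dim must be >= 2", call. = FALSE)
  structure(list(dispersion_ratio = dispersion_ratio,
                 shift_delta = shift_delta,
                 richness_ratio = richness_ratio,
                 n_ref = as.integer(n_ref), n_imp = as.integer(n_imp),
                 latent_dim = as.integer(latent_dim),
                 n_taxa = as.integer(n_taxa),
                 base_abundance = base_abundance),
            class = "sim_truth")
}

#' Simulate one control-impact comparison
#'
#' Draws latent site coordinates under a `sim_truth`, derives a site-by-taxa
#' abundance matrix by mapping latent coordinates onto log-linear taxon
#' loadings and Poisson sampling, thins the impacted group's taxa with
#' retention probability `richness_ratio`, and returns the grouped
#' coordinates both as the exact 2D latent projection and (optionally) via an
#' ordination of the community dissimilarities.
#'
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @param communities if `FALSE`, skip the abundance matrix (and the
#'   ordination) and return latent coordinates only — a fast path for
#'   large-replicate calibration studies.
#' @param ordinate `"pcoa"`, `"nmds"` or `"none"`: ordination applied to the
#'   Bray-Curtis dissimilarities of the simulated communities.
#' @return list with components `latent` (list `points` n x 2, `labels`),
#'   `community` (list `abundances`, `site_labels`, `taxa_ids`, or `NULL`),
#'   `ordination` ([pcoa_2d()]/[nmds_2d()] result or `NULL`), `richness`
#'   (named vector `alpha_ref_mean`, `alpha_imp_mean`, or `NULL`) and `truth`.
#' @export
simulate_comparison <- function(truth, seed = 1L, communities = TRUE,
                                ordinate = c("pcoa", "nmds", "none")) {
  stopifnot(inherits(truth, "sim_truth"))
  ordinate <- match.arg(ordinate)
  set.seed(seed)
  k <- truth$latent_dim
  z_ref <- matrix(stats::rnorm(truth$n_ref * k), truth$n_ref, k)
  z_imp <- matrix(stats::rnorm(truth$n_imp * k, sd = truth$dispersion_ratio),
                  truth$n_imp, k)
  z_imp[, 1] <- z_imp[, 1] + truth$shift_delta
  labels <- c(rep("reference", truth$n_ref), rep("impacted", truth$n_imp))
  z <- rbind(z_ref, z_imp)
  out <- list(latent = list(points = z[, 1:2, drop = FALSE], labels = labels),
              community = NULL, ordination = NULL, richness = NULL,
              truth = truth)
  if (!communities) return(out)

  loadings <- matrix(stats::rnorm(truth$n_taxa * k, sd = 0.4), truth$n_taxa, k)
  log_lambda <- log(truth$base_abundance) + z %*% t(loadings)
  counts <- matrix(stats::rpois(length(log_lambda), exp(log_lambda)),
                   nrow(z), truth$n_taxa)
  retained <- stats::runif(truth$n_taxa) <= truth$richness_ratio
  counts[labels == "impacted", !retained] <- 0L
  # a site must not be empty; give it its most favourable taxon if it is
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    for (i in which(empty)) {
      ok <- if (labels[i] == "impacted") which(retained) else
        seq_len(truth$n_taxa)
      counts[i, ok[which.max(log_lambda[i, ok])]] <- 1L
    }
  }
  rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  colnames(counts) <- paste0("taxon", seq_len(truth$n_taxa))
  out$community <- list(abundances = counts, site_labels = labels,
                        taxa_ids = colnames(counts))
  rich <- rowSums(counts > 0)
  out$richness <- c(alpha_ref_mean = mean(rich[labels == "reference"]),
                    alpha_imp_mean = mean(rich[labels == "impacted"]))
  if (ordinate != "none") {
    d <- dissimilarity_matrix(counts, "bray-curtis")
    out$ordination <- if (ordinate == "pcoa") pcoa_2d(d) else
      nmds_2d(d, seed = seed)
  }
  out
}

#' Pixel-grid specification for the digitization emulator
#'
#' @param width_px,height_px pixel dimensions of the emulated plot (`>= 8`).
#' @param jitter_px half-width of the uniform manual-click error, in pixels
#'   (`>= 0`).
#' @param aspect_distortion multiplicative distortion `a` applied to the
#'   axis-2 pixel scale before quantization. `a = 1` emulates a plot whose
#'   axes share a common unit-per-pixel scale (orthonormal rendering); other
#'   values violate the orthonormal assumption made when mapping pixels back
#'   to coordinates.
#' @return list of class `pixel_spec`.
#' @export
pixel_spec <- function(width_px = 800L, height_px = 600L, jitter_px = 0,
                       aspect_distortion = 1) {
  if (width_px < 8L || height_px < 8L)
    stop("pixel grid must be at least 8 x 8", call. = FALSE)
  if (jitter_px < 0) stop("jitter_px must be >= 0", call. = FALSE)
  if (aspect_distortion <= 0)
    stop("aspect_distortion must be > 0", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 jitter_px = jitter_px,
                 aspect_distortion = aspect_distortion),
            class = "pixel_spec")
}

#' Emulate plot digitization of grouped coordinates
#'
#' Affine-maps coordinates into a pixel grid at a common units-per-pixel scale
#' (axis 2 optionally distorted by `aspect_distortion`), rounds to integer
#' pixels, adds uniform jitter of `plus/minus jitter_px`, then maps back
#' assuming equal units per pixel on both axes — the orthonormal assumption a
#' digitizer must make when the source plot has no graduated axes. With
#' `aspect_distortion = 1` the recovered coordinates differ from a similarity
#' transform of the originals only by quantization and jitter.
#'
#' @param points n x 2 coordinate matrix with at least 2 distinct points.
#' @param labels group labels, passed through unchanged.
#' @param spec a [pixel_spec()].
#' @param seed integer seed for the jitter.
#' @return list with `points` (recovered coordinates) and `labels`.
#' @export
simulate_digitization <- function(points, labels, spec = pixel_spec(),
                                  seed = 1L) {
  stopifnot(inherits(spec, "pixel_spec"))
  points <- as.matrix(points)
  rx <- diff(range(points[, 1]))
  ry <- diff(range(points[, 2]))
  if (rx == 0 && ry == 0)
    stop("degenerate extent: all points coincident", call. = FALSE)
  # common units-per-pixel scale so that the plot fits the grid
  cand <- c(if (rx > 0) (spec$width_px - 1) / rx,
            if (ry > 0) (spec$height_px - 1) / ry)
  s <- min(cand)
  px <- (points[, 1] - min(points[, 1])) * s
  py <- (points[, 2] - min(points[, 2])) * s * spec$aspect_distortion
  px <- round(px); py <- round(py)
  if (spec$jitter_px > 0) {
    set.seed(seed)
    px <- px + stats::runif(length(px), -spec$jitter_px, spec$jitter_px)
    py <- py + stats::runif(length(py), -spec$jitter_px, spec$jitter_px)
  }
  # map back with one pixel-to-unit factor for both axes
  list(points = cbind(axis1 = px / s, axis2 = py / s), labels = labels)
}

# ---- corpus generation -----------------------------------------------------

#' Default fixed effects of the corpus generator
#'
#' Intercepts are the overall effect sizes the meta-analysis is calibrated
#' around (-0.062 for homogeneity, 0.564 for shift, -0.181 for local
#' diversity); all moderator-level deviations default to zero. Supply named
#' numeric vectors per moderator (one value per level, see
#' [ordimeta_levels]) to impose moderator effects.
#'
#' @param response one of `"homogeneity"`, `"shift"`, `"local_diversity"`.
#' @param intercept overall mean of the true effect size.
#' @param biome,pressure,organism,scale named deviation vectors (defaults all
#'   zero).
#' @return list with elements `intercept`, `biome`, `pressure`, `organism`,
#'   `scale`.
#' @export
corpus_beta <- function(response = c("homogeneity", "shift", "local_diversity"),
                        intercept = NULL, biome = NULL, pressure = NULL,
                        organism = NULL, scale = NULL) {
  response <- match.arg(response)
  if (is.null(intercept))
    intercept <- c(homogeneity = -0.062, shift = 0.564,
                   local_diversity = -0.181)[[response]]
  zero <- function(field, x) {
    lv <- ordimeta_levels[[field]]
    out <- stats::setNames(rep(0, length(lv)), lv)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  list(intercept = intercept, biome = zero("biome", biome),
       pressure = zero("pressure", pressure),
       organism = zero("organism", organism), scale = zero("scale", scale))
}

# mean cross-group distance as a function of the impacted offset c is
# f(c) = mean |c - k| over the kinks k = p_j - q_i; convex piecewise linear.
# Solve f(c) = target on the increasing branch, exactly, via prefix sums.
.solve_cross_offset <- function(p, q, target) {
  k <- sort(as.vector(outer(p, q, "-")))
  n <- length(k)
  s <- cumsum(k)
  f_at <- ((2 * seq_len(n) - n) * k + s[n] - 2 * s) / n
  fmin <- min(f_at)
  if (target < fmin) return(NULL)  # infeasible: below the geometric bound
  if (target >= f_at[n]) return(target + s[n] / n)  # beyond the last kink
  j0 <- which.min(f_at)
  # largest kink index j >= j0 with f_at[j] <= target
  j <- max(which(f_at <= target & seq_len(n) >= j0))
  (n * target - s[n] + 2 * s[j]) / (2 * j - n)
}

# equally spaced collinear template with mean pairwise distance exactly m
.template_1d <- function(n, m) {
  p <- seq(0, 1, length.out = n)
  p * (m / mean(stats::dist(p)))
}

#' Simulate a hierarchical meta-analysis corpus with known truth
#'
#' Generates a whole corpus of control-impact comparisons whose *true* effect
#' sizes follow the mixed-model structure the analysis assumes: for each
#' response, true value = moderator fixed effects + publication random
#' intercept `N(0, tau^2)` + design-type intercept + residual `N(0, sigma^2)`.
#' Coordinates are then reverse-engineered (two collinear point clouds with
#' prescribed within/between mean distances) so that [compute_effects()]
#' recovers the drawn true values to machine precision — the meta-model layer
#' can be tested in isolation from community-level sampling noise.
#'
#' True `LRR shift` values are constrained by geometry: non-negativity of the
#' energy distance implies that for point sets in any Euclidean space the mean
#' between-group distance is at least the average of the two with-replacement
#' within-group means, so strongly negative true shifts are unrealizable as
#' point configurations (the floor is about `-log 2` for 2-point groups and
#' rises towards 0 as group sizes grow). Residual draws violating the bound
#' are redrawn, and the redraw count is kept in the truth table; at the
#' default effect sizes a few percent of shift residuals are redrawn, which
#' slightly truncates the lower tail of the realized true shifts — exactly as
#' it must for any corpus of real ordination plots.
#'
#' @param n_publications number of publications `J >= 2`.
#' @param mean_records average comparisons per publication; records per
#'   publication are `1 + Poisson(mean_records - 1)`.
#' @param beta list with elements `homogeneity`, `shift`, `local_diversity`,
#'   each a [corpus_beta()] specification.
#' @param tau between-publication standard deviation of each response.
#' @param sigma residual standard deviation of each response.
#' @param tau_design standard deviation of the design-type intercepts.
#' @param slope_ld numeric `c(homogeneity=, shift=)`: linear dependence of the
#'   two distance-based responses on the record's local-diversity deviation
#'   from its corpus mean (0 = independent responses).
#' @param richness_prob probability a comparison reports a richness pair
#'   (default 1139/3667, the reporting rate the generator emulates).
#' @param residual_model `"constant"` (residual s.d. is `sigma` for every
#'   record) or `"points-scaled"` (s.d. is `sigma * sqrt(26.7 / n_points)`,
#'   emulating noisier effect sizes in smaller studies).
#' @param seed master integer seed; per-record streams are derived from it so
#'   records are reproducible independently.
#' @return list with `dataset` (a [meta_dataset()]) and `truth` (list: per
#'   record table `table` with the drawn true effect sizes, plus `beta`,
#'   `tau`, `sigma`, `tau_design`, `design_effects`, `publication_effects`).
#' @export
simulate_meta_dataset <- function(n_publications = 2133L,
                                  mean_records = 1.72,
                                  beta = list(
                                    homogeneity = corpus_beta("homogeneity"),
                                    shift = corpus_beta("shift"),
                                    local_diversity = corpus_beta("local_diversity")),
                                  tau = 0.2, sigma = 0.3, tau_design = 0.1,
                                  slope_ld = c(homogeneity = 0, shift = 0),
                                  richness_prob = 1139 / 3667,
                                  residual_model = c("constant", "points-scaled"),
                                  seed = 1L) {
  residual_model <- match.arg(residual_model)
  if (n_publications < 2L) stop("need at least 2 publications", call. = FALSE)
  responses <- c("homogeneity", "shift", "local_diversity")
  for (r in responses) {
    b <- beta[[r]]
    if (is.null(b)) stop("beta must have element '", r, "'", call. = FALSE)
    for (f in c("biome", "pressure", "organism", "scale"))
      if (!identical(sort(names(b[[f]])), sort(ordimeta_levels[[f]])))
        stop("beta$", r, "$", f, " must be named with the canonical ", f,
             " levels", call. = FALSE)
  }
  set.seed(seed)
  J <- as.integer(n_publications)
  sizes <- 1L + stats::rpois(J, max(mean_records - 1, 0))
  n_rec <- sum(sizes)
  pub_id <- rep(paste0("pub", seq_len(J)), sizes)
  pub_fx <- sapply(responses, function(r) stats::rnorm(J, 0, tau))
  rownames(pub_fx) <- paste0("pub", seq_len(J))
  des_fx <- sapply(responses,
                   function(r) stats::rnorm(3, 0, tau_design))
  rownames(des_fx) <- ordimeta_levels$design_type
  # publications keep one design type (a study has one design)
  pub_design <- sample(ordimeta_levels$design_type, J, replace = TRUE)
  mods <- data.frame(
    biome = sample(ordimeta_levels$biome, n_rec, replace = TRUE),
    pressure = sample(ordimeta_levels$pressure, n_rec, replace = TRUE),
    organism = sample(ordimeta_levels$organism, n_rec, replace = TRUE),
    scale = sample(ordimeta_levels$scale, n_rec, replace = TRUE),
    stringsAsFactors = FALSE)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n_rec)

  fixed_part <- function(r, i) {
    b <- beta[[r]]
    b$intercept + b$biome[[mods$biome[i]]] + b$pressure[[mods$pressure[i]]] +
      b$organism[[mods$organism[i]]] + b$scale[[mods$scale[i]]]
  }

  ids <- sprintf("cmp%05d", seq_len(n_rec))
  records <- data.frame(comparison_id = ids, publication_id = pub_id,
                        design_type = pub_design[match(pub_id, rownames(pub_fx))],
                        mods, stringsAsFactors = FALSE)
  # accumulate plain vectors; data frames are assembled once at the end
  xs <- vector("list", n_rec)
  nr_vec <- ni_vec <- n_pts <- integer(n_rec)
  hom_vec <- shift_vec <- ld_vec <- redraw_vec <- numeric(n_rec)
  rich_obs <- logical(n_rec)
  alpha_ref_vec <- alpha_imp_vec <- rep(NA_real_, n_rec)

  for (i in seq_len(n_rec)) {
    set.seed(rec_seeds[i])
    n_total <- round(stats::rlnorm(1, meanlog = 2.758, sdlog = 1.027))
    n_total <- min(max(n_total, 4L), 664L)
    n_r <- 2L + stats::rbinom(1, n_total - 4L, 0.5)
    n_i <- n_total - n_r
    sd_i <- if (residual_model == "constant") sigma else
      sigma * sqrt(26.7 / n_total)
    pubj <- pub_fx[pub_id[i], ]
    desj <- des_fx[records$design_type[i], ]
    mu_ld <- fixed_part("local_diversity", i) + pubj["local_diversity"] +
      desj["local_diversity"]
    ld <- mu_ld + stats::rnorm(1, 0, sd_i)
    dev_ld <- ld - beta$local_diversity$intercept
    hom <- fixed_part("homogeneity", i) + pubj["homogeneity"] +
      desj["homogeneity"] + slope_ld[["homogeneity"]] * dev_ld +
      stats::rnorm(1, 0, sd_i)
    mu_shift <- fixed_part("shift", i) + pubj["shift"] + desj["shift"] +
      slope_ld[["shift"]] * dev_ld

    u <- 1
    v <- exp(-hom)
    p <- .template_1d(n_r, u)
    q <- .template_1d(n_i, v)
    p_r <- n_r * (n_r - 1) / 2; p_i <- n_i * (n_i - 1) / 2
    d_w <- (u * p_r + v * p_i) / (p_r + p_i)
    redraws <- 0L
    repeat {
      shift <- mu_shift + stats::rnorm(1, 0, sd_i)
      cc <- .solve_cross_offset(p, q, exp(shift) * d_w)
      if (!is.null(cc)) break
      redraws <- redraws + 1L
      if (redraws > 10000L)
        stop("could not draw a geometrically feasible LRR shift for record ",
             ids[i], call. = FALSE)
    }
    xs[[i]] <- c(p, q + cc)
    nr_vec[i] <- n_r; ni_vec[i] <- n_i; n_pts[i] <- n_total
    hom_vec[i] <- hom; shift_vec[i] <- shift; ld_vec[i] <- ld
    redraw_vec[i] <- redraws
    if (stats::runif(1) <= richness_prob) {
      alpha_ref_vec[i] <- stats::runif(1, 10, 50)
      alpha_imp_vec[i] <- alpha_ref_vec[i] * exp(ld)
      rich_obs[i] <- TRUE
    }
  }
  points <- data.frame(
    comparison_id = rep(ids, n_pts),
    group = unlist(lapply(seq_len(n_rec), function(i)
      rep(c("reference", "impacted"), c(nr_vec[i], ni_vec[i])))),
    axis1 = unlist(xs), axis2 = 0, stringsAsFactors = FALSE)
  truth_tab <- data.frame(
    comparison_id = ids, publication_id = pub_id,
    design_type = records$design_type, mods,
    n_points = n_pts,
    true_lrr_homogeneity = hom_vec, true_lrr_shift = shift_vec,
    true_lrr_local_diversity = ld_vec,
    richness_observed = rich_obs, shift_redraws = as.integer(redraw_vec),
    stringsAsFactors = FALSE)
  richness <- if (any(rich_obs))
    data.frame(comparison_id = ids[rich_obs],
               alpha_ref_mean = alpha_ref_vec[rich_obs],
               alpha_imp_mean = alpha_imp_vec[rich_obs],
               stringsAsFactors = FALSE) else NULL
  dataset <- meta_dataset(records, points, richness,
                          provenance = paste0("simulate_meta_dataset seed=", seed))
  list(dataset = dataset,
       truth = list(table = truth_tab, beta = beta, tau = tau, sigma = sigma,
                    tau_design = tau_design, design_effects = des_fx,
                    publication_effects = pub_fx, seed = seed))
}

#' Censor a corpus to emulate selective publication
#'
#' Each record whose *true* effect size (from the generator's truth table) is
#' below `threshold` in absolute value is removed independently with
#' probability `prob`; records at or above the threshold are always kept.
#'
#' @param dataset a [meta_dataset()] produced by [simulate_meta_dataset()].
#' @param truth the matching truth list (or its `table`).
#' @param prob censoring probability `pi` in `[0, 1]`.
#' @param threshold absolute-effect threshold `t`.
#' @param on which true effect drives the censoring:
#'   `"lrr_homogeneity"`, `"lrr_shift"` or `"lrr_local_diversity"`.
#' @param seed integer seed.
#' @return the censored [meta_dataset()] (possibly empty), provenance updated.
#' @export
inject_publication_bias <- function(dataset, truth, prob, threshold,
                                    on = c("lrr_homogeneity", "lrr_shift",
                                           "lrr_local_diversity"),
                                    seed = 1L) {
  stopifnot(inherits(dataset, "meta_dataset"))
  on <- match.arg(on)
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]", call. = FALSE)
  tab <- if (is.data.frame(truth)) truth else truth$table
  m <- match(dataset$records$comparison_id, tab$comparison_id)
  if (any(is.na(m)))
    stop("truth table does not cover every record", call. = FALSE)
  true_val <- tab[[paste0("true_", on)]][m]
  set.seed(seed)
  censorable <- abs(true_val) < threshold
  drop <- censorable & stats::runif(length(true_val)) < prob
  keep_ids <- dataset$records$comparison_id[!drop]
  meta_dataset(
    records = dataset$records[!drop, , drop = FALSE],
    points = dataset$points[dataset$points$comparison_id %in% keep_ids, ,
                            drop = FALSE],
    richness = if (is.null(dataset$richness)) NULL else
      dataset$richness[dataset$richness$comparison_id %in% keep_ids, ,
                       drop = FALSE],
    provenance = paste0(dataset$provenance, "; censored pi=", prob,
                        " t=", threshold, " on=", on))
}
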