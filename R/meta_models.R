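# Corpus-level synthesis: linear mixed models over the per-comparison effect
# sizes, with a random intercept for publication and one for study design.

.z95 <- 1.959964
.z99 <- 2.575829

# deterministic optimizer settings: bobyqa with a tight final trust region so
# refits (and row permutations) reproduce estimates to ~1e-12
.lmer_ctrl <- function() {
  lme4::lmerControl(optimizer = "bobyqa", optCtrl = list(rhoend = 1e-10),
                    check.conv.singular = lme4::.makeCC(action = "ignore",
                                                        tol = 1e-4))
}

# residual mean square of the fixed-effects-only least-squares fit; a value
# indistinguishable from zero means the response is an exact function of the
# fixed design (noiseless synthetic input) and REML is degenerate
.is_noiseless <- function(lm0, y) {
  s2 <- stats::deviance(lm0) / max(1, stats::df.residual(lm0))
  s2 < 1e-20 * (mean(y^2) + 1e-12)
}

# effects table + moderators, merged and ready for model fitting
.model_frame <- function(dataset, effects, response) {
  if (is.null(effects)) effects <- compute_effects(dataset)
  df <- merge(dataset$records, effects, by = "comparison_id", sort = FALSE)
  df <- df[is.finite(df[[response]]), , drop = FALSE]
  for (f in c("biome", "pressure", "organism", "scale"))
    df[[f]] <- factor(df[[f]], levels = ordimeta_levels[[f]])
  df$publication_id <- factor(df$publication_id)
  df$design_type <- factor(df$design_type, levels = ordimeta_levels$design_type)
  droplevels(df)
}

#' Fit the corpus-level linear mixed model
#'
#' Fits, by REML, a linear mixed model for one effect size with the given
#' categorical moderators as fixed effects and two crossed random intercepts —
#' publication and study design type. Unweighted by default; the sensitivity
#' variant weights each comparison by the square root of its number of
#' extracted points.
#'
#' @param dataset a [meta_dataset()].
#' @param response `"lrr_homogeneity"`, `"lrr_shift"` or
#'   `"lrr_local_diversity"`.
#' @param moderators character vector among `"biome"`, `"pressure"`,
#'   `"organism"`, `"scale"`; may be empty (intercept-only model).
#' @param weights `NULL` (unweighted, the default) or `"sqrt_n"` for
#'   square-root-of-points weights.
#' @param effects optional precomputed [compute_effects()] table (computed
#'   from `dataset` when missing).
#' @return list of class `mixed_model_result`: coefficient table (`coefficients`:
#'   estimate, se), `vcov`, `assign` (term index per coefficient), `terms`
#'   (term labels), random-intercept variances (`var_publication`,
#'   `var_design`, `var_residual`), `boundary` flag (a variance estimated at
#'   the zero boundary), `n`, `n_publications`, `response`, `method`, and the
#'   underlying `lme4` fit in `$fit`.
#' @export
fit_mixed_model <- function(dataset, response = c("lrr_homogeneity",
                                                  "lrr_shift",
                                                  "lrr_local_diversity"),
                            moderators = c("biome", "pressure", "organism",
                                           "scale"),
                            weights = NULL, effects = NULL) {
  response <- match.arg(response)
  stopifnot(inherits(dataset, "meta_dataset"))
  if (length(moderators))
    moderators <- match.arg(moderators, c("biome", "pressure", "organism",
                                          "scale"), several.ok = TRUE)
  df <- .model_frame(dataset, effects, response)
  if (nrow(df) == 0L)
    stop("no usable rows for response ", response, call. = FALSE)
  if (nlevels(df$publication_id) < 2L)
    stop("need at least 2 publications to fit the mixed model", call. = FALSE)
  fixed <- if (length(moderators))
    paste(moderators, collapse = " + ") else "1"
  form <- stats::as.formula(paste0(
    response, " ~ ", fixed, " + (1 | publication_id) + (1 | design_type)"))
  w <- NULL
  if (!is.null(weights)) {
    if (!identical(weights, "sqrt_n"))
      stop("weights must be NULL or \"sqrt_n\"", call. = FALSE)
    w <- sqrt(df$n_points)
  }
  # rank check on the fixed design before handing to lme4
  X <- stats::model.matrix(stats::as.formula(paste0("~ ", fixed)), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased level(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n_par <- ncol(X)
  if (nrow(df) < n_par + 3L)
    stop("too few rows (", nrow(df), ") for ", n_par, " fixed parameters",
         call. = FALSE)
  df$.w <- w
  # degenerate noiseless input: the response is an exact function of the
  # fixed design; variances are all zero (boundary) and the mixed fit reduces
  # to ordinary least squares
  lm0 <- if (is.null(w)) stats::lm(stats::as.formula(paste0(response, " ~ ",
                                                            fixed)), df)
    else stats::lm(stats::as.formula(paste0(response, " ~ ", fixed)), df,
                   weights = .w)
  if (.is_noiseless(lm0, df[[response]])) {
    est <- stats::coef(lm0)
    V <- suppressWarnings(stats::vcov(lm0))
    return(structure(list(
      response = response,
      coefficients = data.frame(term = names(est),
                                estimate = as.numeric(est),
                                se = sqrt(diag(V)), stringsAsFactors = FALSE),
      vcov = V, assign = attr(X, "assign"),
      terms = attr(stats::terms(stats::as.formula(paste0("~ ", fixed))),
                   "term.labels"),
      var_publication = 0, var_design = 0,
      var_residual = stats::deviance(lm0) / max(1, stats::df.residual(lm0)),
      boundary = TRUE,
      n = nrow(df), n_publications = nlevels(df$publication_id),
      method = "OLS (noiseless degenerate input)", weighted = !is.null(w),
      fit = lm0), class = "mixed_model_result"))
  }
  fit <- if (is.null(w))
    lme4::lmer(form, data = df, REML = TRUE, control = .lmer_ctrl()) else
    lme4::lmer(form, data = df, REML = TRUE, weights = .w,
               control = .lmer_ctrl())
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else NA_real_
  }
  est <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  coef_tab <- data.frame(term = names(est), estimate = as.numeric(est),
                         se = sqrt(diag(V)), stringsAsFactors = FALSE)
  structure(list(
    response = response,
    coefficients = coef_tab,
    vcov = V,
    assign = attr(X, "assign"),
    terms = attr(stats::terms(stats::as.formula(paste0("~ ", fixed))),
                 "term.labels"),
    var_publication = getv("publication_id"),
    var_design = getv("design_type"),
    var_residual = getv("Residual"),
    boundary = lme4::isSingular(fit),
    n = nrow(df), n_publications = nlevels(df$publication_id),
    method = "REML", weighted = !is.null(w),
    fit = fit),
    class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Linear mixed model (", x$method, if (x$weighted) ", sqrt-n weighted",
      ") for ", x$response, "\n", sep = "")
  cat("  n =", x$n, "comparisons from", x$n_publications, "publications\n")
  print(x$coefficients, row.names = FALSE)
  cat("  variances: publication", format(x$var_publication, digits = 4),
      "| design", format(x$var_design, digits = 4),
      "| residual", format(x$var_residual, digits = 4),
      if (x$boundary) "(boundary fit)", "\n")
  invisible(x)
}

#' Type II Wald chi-square test of a moderator
#'
#' Joint Wald test that the coefficient block of one factor is zero, adjusted
#' for all other model terms: `chi2 = b' V^-1 b` on the factor's coefficients,
#' with degrees of freedom equal to the block size and a two-sided p-value
#' from the upper tail of the chi-square distribution. With no interactions in
#' the model this is the Type II test.
#'
#' @param model a [fit_mixed_model()] result.
#' @param factor name of a moderator present in the model.
#' @return list of class `wald_test` with `factor`, `chi2`, `df`, `p`.
#' @export
wald_type2 <- function(model, factor) {
  stopifnot(inherits(model, "mixed_model_result"))
  k <- match(factor, model$terms)
  if (is.na(k))
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  idx <- which(model$assign == k)
  b <- model$coefficients$estimate[idx]
  V <- model$vcov[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance block for factor ", factor, call. = FALSE))
  chi2 <- drop(t(b) %*% Vi %*% b)
  df <- length(idx)
  structure(list(factor = factor, chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Type II Wald test, %s: chi2 = %.3f, df = %d, p = %.4g\n",
              x$factor, x$chi2, x$df, x$p))
  invisible(x)
}

#' Estimated marginal means of a single moderator
#'
#' Fits the single-moderator mixed model (same two random intercepts as
#' [fit_mixed_model()]) and returns the model-implied population mean per
#' factor level with normal-quantile 95% and 99% confidence intervals
#' (z = 1.959964 and 2.575829). Pass `factor = NULL` for the overall
#' (intercept-only) marginal mean.
#'
#' @inheritParams fit_mixed_model
#' @param factor one of `"biome"`, `"pressure"`, `"organism"`, `"scale"`, or
#'   `NULL` for the overall mean.
#' @return data.frame of class `emm_table`: `level`, `estimate`, `se`,
#'   `ci95_lo`, `ci95_hi`, `ci99_lo`, `ci99_hi`, `n_comparisons`, `n_studies`,
#'   `low_n` (fewer than 2 comparisons at the level).
#' @export
marginal_means <- function(dataset, response = c("lrr_homogeneity",
                                                 "lrr_shift",
                                                 "lrr_local_diversity"),
                           factor = NULL, weights = NULL, effects = NULL) {
  response <- match.arg(response)
  df <- .model_frame(dataset, effects, response)
  if (is.null(factor)) {
    mod <- fit_mixed_model(dataset, response, moderators = character(0),
                           weights = weights, effects = effects)
    est <- mod$coefficients$estimate[1]
    se <- mod$coefficients$se[1]
    out <- data.frame(level = "all", estimate = est, se = se,
                      n_comparisons = mod$n, n_studies = mod$n_publications,
                      stringsAsFactors = FALSE)
  } else {
    factor <- match.arg(factor, c("biome", "pressure", "organism", "scale"))
    # cell-means parameterization: each coefficient is a level's marginal mean
    form <- stats::as.formula(paste0(
      response, " ~ 0 + ", factor,
      " + (1 | publication_id) + (1 | design_type)"))
    w <- if (is.null(weights)) NULL else sqrt(df$n_points)
    df$.w <- w
    cell_form <- stats::as.formula(paste0(response, " ~ 0 + ", factor))
    lm0 <- if (is.null(w)) stats::lm(cell_form, df) else
      stats::lm(cell_form, df, weights = .w)
    if (.is_noiseless(lm0, df[[response]])) {
      est <- stats::coef(lm0)
      se <- sqrt(diag(suppressWarnings(stats::vcov(lm0))))
    } else {
      fit <- if (is.null(w))
        lme4::lmer(form, data = df, REML = TRUE, control = .lmer_ctrl()) else
        lme4::lmer(form, data = df, REML = TRUE, weights = .w,
                   control = .lmer_ctrl())
      est <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    }
    lev <- sub(paste0("^", factor), "", names(est))
    n_cmp <- as.integer(table(df[[factor]])[lev])
    n_std <- vapply(lev, function(l)
      length(unique(df$publication_id[df[[factor]] == l])), integer(1))
    out <- data.frame(level = lev, estimate = as.numeric(est), se = se,
                      n_comparisons = n_cmp, n_studies = n_std,
                      stringsAsFactors = FALSE)
    low <- out$n_comparisons < 2L
    if (any(low))
      warning("level(s) with fewer than 2 comparisons: ",
              paste(out$level[low], collapse = ", "))
  }
  out$ci95_lo <- out$estimate - .z95 * out$se
  out$ci95_hi <- out$estimate + .z95 * out$se
  out$ci99_lo <- out$estimate - .z99 * out$se
  out$ci99_hi <- out$estimate + .z99 * out$se
  out$low_n <- out$n_comparisons < 2L
  out <- out[, c("level", "estimate", "se", "ci95_lo", "ci95_hi",
                 "ci99_lo", "ci99_hi", "n_comparisons", "n_studies", "low_n")]
  class(out) <- c("emm_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Regression of a distance-based effect size on local diversity change
#'
#' Mixed regression of `lrr_homogeneity` or `lrr_shift` on
#' `lrr_local_diversity` with a random intercept for publication, restricted
#' to comparisons where both effect sizes are available. The global slope is
#' tested with a Type II Wald chi-square (1 df); the same regression is then
#' refit on the subset of records at each level of each of the four
#' moderators.
#'
#' @inheritParams fit_mixed_model
#' @param min_subset_n subsets smaller than this are flagged `low_n`
#'   (default 10).
#' @return list of class `lrr_regression`: `slope`, `se`, `wald` (a
#'   `wald_test`), `n`, and `subsets` — a data.frame with `factor`, `level`,
#'   `slope`, `se`, `n`, `low_n`.
#' @export
regress_lrr <- function(dataset, response = c("lrr_homogeneity", "lrr_shift"),
                        effects = NULL, min_subset_n = 10L) {
  response <- match.arg(response)
  if (is.null(effects)) effects <- compute_effects(dataset)
  df <- .model_frame(dataset, effects, response)
  df <- df[is.finite(df$lrr_local_diversity), , drop = FALSE]
  if (nrow(df) < 4L)
    stop("too few comparisons with both effect sizes", call. = FALSE)
  fit1 <- function(d) {
    if (stats::var(d$lrr_local_diversity) == 0)
      return(c(NA_real_, NA_real_))  # slope unidentifiable in this subset
    lm0 <- stats::lm(stats::as.formula(paste0(response,
                                              " ~ lrr_local_diversity")), d)
    if (.is_noiseless(lm0, d[[response]])) {
      est <- stats::coef(lm0)
      V <- suppressWarnings(stats::vcov(lm0))  # exact fit: near-zero s.e.
      return(c(est[["lrr_local_diversity"]],
               sqrt(diag(V))[["lrr_local_diversity"]]))
    }
    form <- stats::as.formula(paste0(response,
      " ~ lrr_local_diversity + (1 | publication_id)"))
    fit <- tryCatch(lme4::lmer(form, data = d, REML = TRUE,
                               control = .lmer_ctrl()),
                    error = function(e) NULL)
    if (is.null(fit) ||
        !("lrr_local_diversity" %in% names(lme4::fixef(fit))))
      return(c(NA_real_, NA_real_))
    V <- as.matrix(stats::vcov(fit))
    j <- match("lrr_local_diversity", names(lme4::fixef(fit)))
    c(lme4::fixef(fit)[[j]], sqrt(diag(V))[j])
  }
  g <- fit1(df)
  chi2 <- (g[1] / g[2])^2
  wald <- structure(list(factor = "lrr_local_diversity", chi2 = chi2, df = 1L,
                         p = stats::pchisq(chi2, 1, lower.tail = FALSE)),
                    class = "wald_test")
  subs <- list()
  for (f in c("biome", "pressure", "organism", "scale")) {
    for (l in levels(df[[f]])) {
      d <- df[df[[f]] == l, , drop = FALSE]
      est <- if (nrow(d) >= 4L) fit1(d) else c(NA_real_, NA_real_)
      subs[[length(subs) + 1L]] <- data.frame(
        factor = f, level = l, slope = est[1], se = est[2], n = nrow(d),
        low_n = nrow(d) < min_subset_n, stringsAsFactors = FALSE)
    }
  }
  structure(list(response = response, slope = g[1], se = g[2], wald = wald,
                 n = nrow(df), subsets = do.call(rbind, subs)),
            class = "lrr_regression")
}

#' @export
print.lrr_regression <- function(x, ...) {
  cat(sprintf("%s ~ lrr_local_diversity: slope = %.4f (se %.4f), n = %d\n",
              x$response, x$slope, x$se, x$n))
  print(x$wald)
  invisible(x)
}
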