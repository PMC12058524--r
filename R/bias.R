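# Publication-bias battery: funnel asymmetry, Rosenthal fail-safe N, p-curve.
#
# The corpus carries no per-comparison standard errors (effect sizes are
# extracted from published plots), so precision proxies and per-comparison
# z/p values are constructed: precision defaults to sqrt(points per
# comparison), and z comes from a within-comparison bootstrap of the effect
# size (see effect_tests). Both are documented proxies with user override.

#' Funnel data and Egger-style asymmetry regression
#'
#' Pairs every effect with a precision proxy and fits the unweighted
#' least-squares regression of effect on 1/precision; the slope (with its
#' standard error) is an asymmetry statistic in the spirit of Egger's test —
#' a convenience summary of the funnel, not a calibrated test.
#'
#' @param effect numeric vector of effect sizes.
#' @param precision numeric precision proxy per effect (default
#'   `sqrt(n_points)` if `n_points` given).
#' @param n_points optional number of extracted points per comparison, used
#'   for the default precision proxy.
#' @return list of class `funnel_result`: `data` (data.frame `effect`,
#'   `precision`, `inv_precision`), `slope`, `se`, `t`.
#' @export
funnel_data <- function(effect, precision = NULL, n_points = NULL) {
  ok <- is.finite(effect)
  if (is.null(precision)) {
    if (is.null(n_points))
      stop("supply precision or n_points", call. = FALSE)
    precision <- sqrt(n_points)
  }
  effect <- effect[ok]; precision <- precision[ok]
  if (length(effect) < 10L)
    stop("need at least 10 effects for a funnel", call. = FALSE)
  if (length(unique(precision)) < 2L)
    stop("asymmetry slope undefined: precision is constant", call. = FALSE)
  x <- 1 / precision
  fit <- stats::lm(effect ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  structure(list(
    data = data.frame(effect = effect, precision = precision,
                      inv_precision = x),
    slope = unname(sm["x", "Estimate"]),
    se = unname(sm["x", "Std. Error"]),
    t = unname(sm["x", "t value"])),
    class = "funnel_result")
}

#' Rosenthal fail-safe N (file drawer analysis)
#'
#' Number of unpublished null results required to bring the pooled
#' (Stouffer-combined) effect down to the one-sided significance threshold:
#' `N = floor((sum z)^2 / z_alpha^2 - k)`, clipped at zero.
#'
#' @param z numeric vector of per-result standard-normal deviates (`k >= 1`).
#' @param alpha one-sided significance level (default 0.05).
#' @return non-negative integer.
#' @examples
#' fail_safe_n(c(2, 2, 2))  # 10
#' @export
fail_safe_n <- function(z, alpha = 0.05) {
  if (length(z) < 1L || any(!is.finite(z)))
    stop("z must be a non-empty vector of finite values", call. = FALSE)
  if (sum(z) <= 0) return(0L)  # pooled effect points the wrong way
  z_a <- stats::qnorm(1 - alpha)
  n <- floor(sum(z)^2 / z_a^2 - length(z))
  as.integer(max(n, 0))
}

#' P-curve analysis (full curve, Stouffer test)
#'
#' Keeps the significant p-values (`p < 0.05`), rescales them to
#' `pp = p / 0.05`, and combines `Z = sum(qnorm(pp)) / sqrt(k)` with one-sided
#' `p = pnorm(Z)`. `Z < 0` indicates right skew — an excess of very small
#' p-values, i.e. evidential value rather than selective reporting.
#'
#' @param p numeric vector of p-values in `(0, 1)`.
#' @return list of class `pcurve_result`: `k` (number of significant results),
#'   `z` (Stouffer Z), `p` (one-sided), `applicable` (`FALSE` when no input
#'   p-value is below 0.05, with `z` and `p` set to `NA`).
#' @examples
#' p_curve(c(0.01, 0.02))
#' @export
p_curve <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("p-values must lie strictly in (0, 1)", call. = FALSE)
  sig <- p[p < 0.05]
  if (length(sig) == 0L) {
    warning("no p-values below 0.05; p-curve not applicable")
    return(structure(list(k = 0L, z = NA_real_, p = NA_real_,
                          applicable = FALSE), class = "pcurve_result"))
  }
  pp <- sig / 0.05
  z <- sum(stats::qnorm(pp)) / sqrt(length(pp))
  structure(list(k = length(sig), z = z, p = stats::pnorm(z),
                 applicable = TRUE), class = "pcurve_result")
}

#' Per-comparison z and p values via within-comparison bootstrap
#'
#' The corpus reports no per-comparison uncertainty, so a resampling proxy is
#' constructed: points are resampled with replacement within each group, the
#' effect size is recomputed, and the bootstrap standard deviation yields
#' `z = effect / se` with a two-sided normal p-value. These feed
#' [fail_safe_n()] and [p_curve()].
#'
#' @param dataset a [meta_dataset()].
#' @param response `"lrr_homogeneity"` or `"lrr_shift"`.
#' @param n_boot bootstrap replicates per comparison (default 200).
#' @param seed integer seed.
#' @return data.frame `comparison_id`, `effect`, `se`, `z`, `p` (rows with an
#'   undefined effect or zero bootstrap spread are dropped).
#' @export
effect_tests <- function(dataset, response = c("lrr_homogeneity", "lrr_shift"),
                         n_boot = 200L, seed = 1L) {
  response <- match.arg(response)
  stopifnot(inherits(dataset, "meta_dataset"))
  eff <- compute_effects(dataset)
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(eff))) {
    est <- eff[[response]][i]
    if (!is.finite(est)) next
    id <- eff$comparison_id[i]
    sel <- dataset$points$comparison_id == id
    pts <- as.matrix(dataset$points[sel, c("axis1", "axis2")])
    lab <- dataset$points$group[sel]
    ref <- which(lab == "reference"); imp <- which(lab == "impacted")
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      take <- c(sample(ref, length(ref), replace = TRUE),
                sample(imp, length(imp), replace = TRUE))
      s <- pairwise_group_means(pts[take, , drop = FALSE], lab[take],
                                check = FALSE)
      boots[b] <- if (response == "lrr_homogeneity") {
        if (is.finite(s$D_I_bar) && is.finite(s$D_R_bar) &&
            s$D_I_bar > 0 && s$D_R_bar > 0) -log(s$D_I_bar / s$D_R_bar)
        else NA_real_
      } else {
        if (is.finite(s$D_B_bar) && is.finite(s$D_W_bar) &&
            s$D_B_bar > 0 && s$D_W_bar > 0) log(s$D_B_bar / s$D_W_bar)
        else NA_real_
      }
    }
    se <- stats::sd(boots, na.rm = TRUE)
    if (!is.finite(se) || se == 0) next
    z <- est / se
    out[[length(out) + 1L]] <- data.frame(
      comparison_id = id, effect = est, se = se, z = z,
      p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Publication-bias report for one response
#'
#' Runs the full battery — funnel asymmetry, Rosenthal fail-safe N on the
#' per-comparison z values, and the p-curve on the per-comparison p values —
#' for one distance-based effect size.
#'
#' @inheritParams effect_tests
#' @param alpha one-sided level for the fail-safe N.
#' @return list of class `bias_report` with `funnel`, `failsafe_n`, `pcurve`
#'   and the per-comparison `tests` table.
#' @export
bias_report <- function(dataset, response = c("lrr_homogeneity", "lrr_shift"),
                        n_boot = 200L, alpha = 0.05, seed = 1L) {
  response <- match.arg(response)
  tests <- effect_tests(dataset, response, n_boot = n_boot, seed = seed)
  eff <- compute_effects(dataset)
  ok <- is.finite(eff[[response]])
  funnel <- funnel_data(eff[[response]][ok], n_points = eff$n_points[ok])
  structure(list(
    response = response,
    funnel = funnel,
    failsafe_n = fail_safe_n(tests$z, alpha = alpha),
    pcurve = suppressWarnings(p_curve(tests$p)),
    tests = tests), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Publication-bias battery for", x$response, "\n")
  cat(sprintf("  funnel asymmetry slope: %.4f (se %.4f, t = %.2f)\n",
              x$funnel$slope, x$funnel$se, x$funnel$t))
  cat("  fail-safe N:", x$failsafe_n, "\n")
  if (x$pcurve$applicable)
    cat(sprintf("  p-curve: k = %d, Z = %.4f, p = %.4f\n",
                x$pcurve$k, x$pcurve$z, x$pcurve$p))
  else cat("  p-curve: not applicable (no significant results)\n")
  invisible(x)
}
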