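#' Community dissimilarity matrix
#'
#' Computes a site-by-site dissimilarity matrix from a site-by-taxa abundance
#' matrix: Bray-Curtis (`sum|x-y| / sum(x+y)`), Jaccard on presence/absence
#' (`1 - |intersection|/|union|`) or Euclidean distance. Bray-Curtis and
#' Jaccard are delegated to [vegan::vegdist()].
#'
#' @param x numeric matrix, sites in rows, taxa in columns. Bray-Curtis and
#'   Jaccard require non-negative entries and no all-zero site.
#' @param metric one of `"bray-curtis"`, `"jaccard"`, `"euclidean"`.
#' @return symmetric numeric matrix with zero diagonal and `dimnames` taken
#'   from `rownames(x)`.
#' @export
dissimilarity_matrix <- function(x, metric = c("bray-curtis", "jaccard",
                                               "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 sites", call. = FALSE)
  if (metric %in% c("bray-curtis", "jaccard")) {
    if (any(x < 0)) stop(metric, " requires non-negative abundances", call. = FALSE)
    zero <- rowSums(x) == 0
    if (any(zero))
      stop("distance undefined for all-zero site(s): ",
           paste(if (is.null(rownames(x))) which(zero) else rownames(x)[zero],
                 collapse = ", "), call. = FALSE)
  }
  d <- switch(metric,
    "bray-curtis" = vegan::vegdist(x, method = "bray"),
    "jaccard" = vegan::vegdist(x > 0, method = "jaccard"),
    "euclidean" = stats::dist(x))
  m <- as.matrix(d)
  dimnames(m) <- list(rownames(x), rownames(x))
  m
}

# validate a square distance matrix; returns it with zero diagonal
.check_dist <- function(d, n_min = 3L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) < n_min)
    stop("need at least ", n_min, " sites for ordination", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(d)))
    stop("distance matrix must be symmetric", call. = FALSE)
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (2D)
#'
#' Metric embedding of a distance matrix: the squared distances are double
#' centred (`-d^2/2`, centred by row and column means), eigendecomposed, and
#' the coordinates on the two largest positive eigenvalues are returned,
#' scaled by the square root of their eigenvalue. No correction is applied for
#' negative eigenvalues (published 2D plots show the two leading positive axes
#' only). The sign of each axis is fixed so that its largest-magnitude loading
#' is positive, making outputs reproducible bit-for-bit.
#'
#' @param d square symmetric distance matrix (or `dist`), `n >= 3`.
#' @return list of class `ordination_result` with `coordinates` (n x 2),
#'   `eigenvalues` (all, descending), `method = "PCoA"`, `converged = TRUE`.
#' @export
pcoa_2d <- function(d) {
  d <- .check_dist(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  # double centring
  rm <- rowMeans(a); gm <- mean(a)
  g <- a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  if (sum(pos) < 2L)
    stop("rank-deficient configuration: fewer than 2 positive eigenvalues; ",
         "jitter the input or use NMDS", call. = FALSE)
  coords <- e$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(e$values[1:2]), 2)
  for (k in 1:2) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, eigenvalues = e$values,
                 method = "PCoA", stress = NA_real_, converged = TRUE,
                 restarts_used = 0L),
            class = "ordination_result")
}

#' Kruskal stress-1 of a configuration
#'
#' Evaluates `sqrt(sum((dhat - dstar)^2) / sum(dhat^2))` for a 2D
#' configuration against a target dissimilarity matrix, where `dhat` are the
#' configuration's Euclidean distances and `dstar` the monotone (isotonic)
#' regression of `dhat` on the rank order of the dissimilarities (primary tie
#' handling).
#'
#' @param d target dissimilarity matrix.
#' @param coordinates n x 2 configuration.
#' @return stress-1 value in `[0, 1]`.
#' @export
kruskal_stress <- function(d, coordinates) {
  d <- .check_dist(d)
  coordinates <- as.matrix(coordinates)
  lo <- lower.tri(d)
  diss <- d[lo]
  dhat <- as.matrix(stats::dist(coordinates))[lo]
  ord <- order(diss, dhat)  # primary ties: free ordering within tie blocks
  fit <- stats::isoreg(dhat[ord])$yf
  dstar <- numeric(length(dhat)); dstar[ord] <- fit
  sqrt(sum((dhat - dstar)^2) / sum(dhat^2))
}

#' Non-metric multidimensional scaling (2D)
#'
#' Rank-based 2D embedding minimizing Kruskal stress-1 (global NMDS with
#' monotone-regression disparities, primary tie handling), via
#' [vegan::monoMDS()]. The best configuration over `restarts` random starts
#' plus one start from the [pcoa_2d()] solution is returned.
#'
#' @param d square symmetric dissimilarity matrix (or `dist`), `n >= 4`.
#' @param restarts number of random starts (`>= 1`), default 20.
#' @param max_iter maximum iterations per start, default 300.
#' @param tol convergence tolerance on the stress change, default 1e-6.
#' @param seed integer seed controlling the random starts.
#' @return list of class `ordination_result` with `coordinates`, `stress`
#'   (stress-1, in `[0, 1]`), `method = "NMDS"`, `converged` and
#'   `restarts_used`. Non-convergence in all starts is reported with
#'   `converged = FALSE` and a warning, never an error.
#' @export
nmds_2d <- function(d, restarts = 20L, max_iter = 300L, tol = 1e-6,
                    seed = 1L) {
  d <- .check_dist(d, n_min = 4L)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  dd <- stats::as.dist(d)
  n <- nrow(d)
  run1 <- function(init) {
    fit <- vegan::monoMDS(dd, y = init, k = 2, model = "global",
                          maxit = max_iter, sratmax = 1 - tol,
                          smin = 1e-8, sfgrmin = 1e-12)
    list(points = fit$points, stress = fit$stress,
         converged = fit$icause %in% c(2L, 3L, 4L))
  }
  starts <- list(pcoa_2d(d)$coordinates)
  set.seed(seed)
  for (r in seq_len(restarts))
    starts <- c(starts, list(matrix(stats::rnorm(2 * n), n, 2)))
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    res <- tryCatch(run1(s), error = function(e) NULL)
    if (is.null(res)) next
    any_conv <- any_conv || res$converged
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  if (is.null(best))
    stop("NMDS failed in all restarts", call. = FALSE)
  if (!any_conv)
    warning("NMDS did not converge in any restart; returning best configuration")
  coords <- best$points
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, eigenvalues = NULL,
                 method = "NMDS", stress = best$stress,
                 converged = any_conv, restarts_used = length(starts)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(x$method, "ordination:", nrow(x$coordinates), "sites in 2 dimensions\n")
  if (x$method == "NMDS")
    cat("  stress-1:", format(x$stress, digits = 5),
        if (x$converged) "(converged)" else "(NOT converged)", "\n")
  else
    cat("  first eigenvalues:",
        paste(format(utils::head(x$eigenvalues, 3), digits = 5), collapse = ", "),
        "\n")
  invisible(x)
}
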