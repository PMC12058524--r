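#' Sensitivity of the effect sizes to extra groups in the source ordination
#'
#' The two distance-based effect sizes are computed from 2D ordinations that
#' may contain more than the two focal groups; extra groups change the
#' dissimilarity structure the ordination must accommodate and can therefore
#' distort the focal distances. This experiment quantifies that distortion:
#' per replicate, `G` groups of communities are simulated in latent space (the
#' two focal groups per `truth`, plus `G - 2` decoy groups displaced in random
#' latent directions), the focal-only and the all-group latent distance
#' matrices are ordinated separately, and the focal effect sizes from the two
#' ordinations are compared.
#'
#' With `latent_dim = 2` and PCoA the configuration is planar, both
#' ordinations reproduce the latent distances exactly, and the paired
#' difference is zero up to numerical noise; distortion can only arise from
#' latent dimensionality the 2D plot cannot show.
#'
#' @param truth a [sim_truth()] for the two focal groups. Defaults to a
#'   clearly non-null configuration (`dispersion_ratio = 0.5`,
#'   `shift_delta = 1.5`, `latent_dim = 6`) so that sign agreement is a
#'   meaningful summary.
#' @param n_groups total number of groups `G >= 3`.
#' @param decoy_displacement distance of each decoy group's centroid from the
#'   latent origin (default 1.5, same order as the focal shift).
#' @param replicates number of replicates (`>= 1`).
#' @param ordination `"pcoa"` or `"nmds"`. The NMDS branch uses matched seeds
#'   for the focal-only and all-group runs so differences reflect group
#'   inclusion, not restart luck.
#' @param seed master integer seed.
#' @return data.frame of class `robustness_table`, one row per replicate:
#'   `hom_focal`, `shift_focal` (focal-only ordination), `hom_all`,
#'   `shift_all` (all-group ordination), `d_hom`, `d_shift` (paired
#'   differences). Replicates whose ordination fails are skipped and counted
#'   in `attr(, "skipped")`.
#' @seealso [summarize_robustness()]
#' @export
group_inclusion_experiment <- function(truth = sim_truth(dispersion_ratio = 0.5,
                                                         shift_delta = 1.5,
                                                         latent_dim = 6L),
                                       n_groups = 4L,
                                       decoy_displacement = 1.5,
                                       replicates = 100L,
                                       ordination = c("pcoa", "nmds"),
                                       seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  ordination <- match.arg(ordination)
  if (n_groups < 3L)
    stop("the experiment needs at least 3 groups (G >= 3)", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  k <- truth$latent_dim
  n_focal <- truth$n_ref + truth$n_imp
  rows <- list(); skipped <- 0L
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    z_ref <- matrix(stats::rnorm(truth$n_ref * k), truth$n_ref, k)
    z_imp <- matrix(stats::rnorm(truth$n_imp * k,
                                 sd = truth$dispersion_ratio),
                    truth$n_imp, k)
    z_imp[, 1] <- z_imp[, 1] + truth$shift_delta
    decoys <- list()
    for (g in seq_len(n_groups - 2L)) {
      dir <- stats::rnorm(k); dir <- dir / sqrt(sum(dir^2))
      centre <- decoy_displacement * dir
      decoys[[g]] <- sweep(matrix(stats::rnorm(truth$n_ref * k),
                                  truth$n_ref, k), 2, centre, "+")
    }
    z_all <- rbind(z_ref, z_imp, do.call(rbind, decoys))
    labels <- c(rep("reference", truth$n_ref), rep("impacted", truth$n_imp))
    d_focal <- as.matrix(stats::dist(z_all[seq_len(n_focal), , drop = FALSE]))
    d_all <- as.matrix(stats::dist(z_all))
    ord <- function(d) {
      if (ordination == "pcoa") pcoa_2d(d) else
        nmds_2d(d, seed = rep_seeds[r])
    }
    res <- tryCatch({
      o_focal <- ord(d_focal)
      o_all <- ord(d_all)
      s_f <- pairwise_group_means(o_focal$coordinates, labels)
      s_a <- pairwise_group_means(
        o_all$coordinates[seq_len(n_focal), , drop = FALSE], labels)
      c(hom_focal = lrr_homogeneity(s_f), shift_focal = lrr_shift(s_f),
        hom_all = lrr_homogeneity(s_a), shift_all = lrr_shift(s_a))
    }, error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- as.data.frame(as.list(res))
  }
  out <- do.call(rbind, rows)
  out$d_hom <- out$hom_all - out$hom_focal
  out$d_shift <- out$shift_all - out$shift_focal
  attr(out, "skipped") <- skipped
  attr(out, "parameters") <- list(truth = truth, n_groups = n_groups,
                                  decoy_displacement = decoy_displacement,
                                  ordination = ordination, seed = seed)
  class(out) <- c("robustness_table", "data.frame")
  out
}

#' Summary of a group-inclusion robustness experiment
#'
#' @param table a `robustness_table` from [group_inclusion_experiment()].
#' @return data.frame with one row per effect size: median absolute paired
#'   difference (`median_abs_diff`), mean paired difference (`mean_diff`) and
#'   the proportion of replicates where the focal-only and all-group effect
#'   sizes agree in sign (`sign_agreement`).
#' @export
summarize_robustness <- function(table) {
  stopifnot(inherits(table, "robustness_table"))
  row <- function(name, a, b) data.frame(
    effect = name,
    median_abs_diff = stats::median(abs(b - a)),
    mean_diff = mean(b - a),
    sign_agreement = mean(sign(a) == sign(b)),
    n = length(a), stringsAsFactors = FALSE)
  rbind(row("lrr_homogeneity", table$hom_focal, table$hom_all),
        row("lrr_shift", table$shift_focal, table$shift_all))
}
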