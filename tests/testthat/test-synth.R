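test_that("exchangeable groups produce LRRs centred at zero (latent path)", {
  truth <- sim_truth()  # r = 1, delta = 0, rho = 1
  n_rep <- 500
  hom <- numeric(n_rep)
  for (i in 1:n_rep) {
    sim <- simulate_comparison(truth, seed = i, communities = FALSE)
    hom[i] <- lrr_homogeneity(pairwise_group_means(sim$latent$points,
                                                   sim$latent$labels))
  }
  expect_lt(abs(mean(hom)), 3 * sd(hom) / sqrt(n_rep))
})

test_that("halved impacted dispersion gives mean LRR homogeneity ln 2", {
  truth <- sim_truth(dispersion_ratio = 0.5)
  n_rep <- 500
  hom <- numeric(n_rep)
  for (i in 1:n_rep) {
    sim <- simulate_comparison(truth, seed = 1000 + i, communities = FALSE)
    hom[i] <- lrr_homogeneity(pairwise_group_means(sim$latent$points,
                                                   sim$latent$labels))
  }
  expect_lt(abs(mean(hom) - log(2)), 3 * sd(hom) / sqrt(n_rep))
})

test_that("taxon thinning at rho = 0.5 gives mean LRR local diversity ln 0.5", {
  truth <- sim_truth(richness_ratio = 0.5, n_taxa = 80, base_abundance = 50)
  n_rep <- 500
  ld <- numeric(n_rep)
  for (i in 1:n_rep) {
    sim <- simulate_comparison(truth, seed = 2000 + i, ordinate = "none")
    ld[i] <- lrr_local_diversity(sim$richness["alpha_ref_mean"],
                                 sim$richness["alpha_imp_mean"])
  }
  expect_lt(abs(mean(ld) - log(0.5)), 3 * sd(ld) / sqrt(n_rep))
})

test_that("mean LRR homogeneity is strictly decreasing in the dispersion ratio", {
  mean_hom <- function(r) {
    truth <- sim_truth(dispersion_ratio = r)
    mean(vapply(1:300, function(i) {
      sim <- simulate_comparison(truth, seed = 3000 + i, communities = FALSE)
      lrr_homogeneity(pairwise_group_means(sim$latent$points,
                                           sim$latent$labels))
    }, numeric(1)))
  }
  ms <- vapply(c(0.5, 1, 2), mean_hom, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("simulated communities carry valid abundances and geometry", {
  sim <- simulate_comparison(sim_truth(shift_delta = 2, n_taxa = 40),
                             seed = 9, ordinate = "pcoa")
  counts <- sim$community$abundances
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  expect_true(all(rowSums(counts) > 0))
  expect_equal(dim(counts), c(20L, 40L))
  expect_s3_class(sim$ordination, "ordination_result")
  # a clear centroid displacement is visible through the ordination
  s <- pairwise_group_means(sim$ordination$coordinates,
                            sim$community$site_labels)
  expect_gt(lrr_shift(s), 0)
  expect_error(simulate_comparison(sim_truth(n_ref = 1)), "n_ref")
})

test_that("corpus generator reproduces its drawn true effect sizes exactly", {
  sim <- simulate_meta_dataset(n_publications = 40, seed = 5,
                               richness_prob = 1)
  eff <- compute_effects(sim$dataset)
  m <- match(eff$comparison_id, sim$truth$table$comparison_id)
  expect_lt(max(abs(eff$lrr_homogeneity -
                    sim$truth$table$true_lrr_homogeneity[m])), 1e-10)
  expect_lt(max(abs(eff$lrr_shift - sim$truth$table$true_lrr_shift[m])), 1e-10)
  expect_lt(max(abs(eff$lrr_local_diversity -
                    sim$truth$table$true_lrr_local_diversity[m])), 1e-10)
})

test_that("noiseless corpus reproduces the level means exactly", {
  b <- list(homogeneity = corpus_beta("homogeneity", intercept = 0,
                                      biome = c(terrestrial = 0.3,
                                                freshwater = -0.2,
                                                marine = 0.1)),
            shift = corpus_beta("shift", intercept = 0.5),
            local_diversity = corpus_beta("local_diversity", intercept = -0.2))
  sim <- simulate_meta_dataset(n_publications = 30, beta = b, tau = 0,
                               sigma = 0, tau_design = 0, seed = 17,
                               richness_prob = 1)
  eff <- compute_effects(sim$dataset)
  df <- merge(sim$dataset$records, eff, by = "comparison_id")
  agg <- tapply(df$lrr_homogeneity, df$biome, mean)
  expect_equal(unname(agg["terrestrial"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(agg["freshwater"]), -0.2, tolerance = 1e-10)
  expect_equal(unname(agg["marine"]), 0.1, tolerance = 1e-10)
  expect_true(all(abs(df$lrr_shift - 0.5) < 1e-10))
})

test_that("records per publication average about 1.72", {
  sim <- simulate_meta_dataset(n_publications = 1000, seed = 23)
  realized <- nrow(sim$dataset$records) / 1000
  expect_lt(abs(realized - 1.72), 0.1)
})

test_that("publication-bias injection censors at the binomial rate", {
  sim <- simulate_meta_dataset(n_publications = 600, seed = 31)
  ds <- sim$dataset
  # pi = 0 leaves the dataset untouched
  same <- inject_publication_bias(ds, sim$truth, prob = 0, threshold = 0.2)
  expect_equal(nrow(same$records), nrow(ds$records))
  # pi = 1 with infinite threshold removes everything
  none <- inject_publication_bias(ds, sim$truth, prob = 1, threshold = Inf)
  expect_equal(nrow(none$records), 0L)
  expect_error(fit_mixed_model(none, "lrr_homogeneity"), "no usable rows")
  # pi = 0.5, t = 0.2: retained count within the binomial 99% interval
  t <- 0.2; p <- 0.5
  n_below <- sum(abs(sim$truth$table$true_lrr_homogeneity) < t)
  n_tot <- nrow(ds$records)
  kept <- inject_publication_bias(ds, sim$truth, prob = p, threshold = t,
                                  seed = 7)
  expected <- n_tot - p * n_below
  half <- qnorm(0.995) * sqrt(n_below * p * (1 - p))
  expect_gt(nrow(kept$records), expected - half)
  expect_lt(nrow(kept$records), expected + half)
})

test_that("digitization is faithful at high resolution and aspect ratio 1", {
  set.seed(13)
  cfg <- random_config(8, 8)
  s0 <- pairwise_group_means(cfg$points, cfg$labels)
  h0 <- lrr_homogeneity(s0); sh0 <- lrr_shift(s0)
  hi <- simulate_digitization(cfg$points, cfg$labels,
                              pixel_spec(1e6, 1e6, jitter_px = 0))
  s1 <- pairwise_group_means(hi$points, hi$labels)
  expect_lt(abs(lrr_homogeneity(s1) - h0), 1e-4)
  expect_lt(abs(lrr_shift(s1) - sh0), 1e-4)
  # uniform rescaling of the source plot leaves the ratios unchanged
  lo_a <- simulate_digitization(cfg$points, cfg$labels, pixel_spec(600, 600))
  lo_b <- simulate_digitization(cfg$points * 37.5, cfg$labels,
                                pixel_spec(600, 600))
  sa <- pairwise_group_means(lo_a$points, lo_a$labels)
  sb <- pairwise_group_means(lo_b$points, lo_b$labels)
  expect_equal(lrr_homogeneity(sa), lrr_homogeneity(sb), tolerance = 1e-12)
  expect_equal(lrr_shift(sa), lrr_shift(sb), tolerance = 1e-12)
  expect_error(simulate_digitization(rbind(c(1, 1), c(1, 1)), c("a", "b"),
                                     pixel_spec()), "coincident")
})

test_that("violating the orthonormal assumption distorts the effect sizes", {
  set.seed(0)
  cfg <- random_config(8, 8)
  cfg$points[cfg$labels == "impacted", 2] <-
    cfg$points[cfg$labels == "impacted", 2] + 2  # shift along axis 2
  s0 <- pairwise_group_means(cfg$points, cfg$labels)
  dig <- simulate_digitization(cfg$points, cfg$labels,
                               pixel_spec(4000, 4000, aspect_distortion = 2))
  s2 <- pairwise_group_means(dig$points, dig$labels)
  # oracle: recompute on coordinates with axis 2 stretched by 2 directly
  stretched <- cfg$points %*% diag(c(1, 2))
  s_or <- pairwise_group_means(stretched, cfg$labels)
  expect_gt(abs(lrr_shift(s2) - lrr_shift(s0)), 1e-3)
  expect_lt(abs(lrr_shift(s2) - lrr_shift(s_or)), 5e-3)
  expect_lt(abs(lrr_homogeneity(s2) - lrr_homogeneity(s_or)), 5e-3)
})
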