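# a small corpus with known moderator effects, shared across tests
known_beta <- function() list(
  homogeneity = corpus_beta("homogeneity", intercept = -0.1,
                            biome = c(terrestrial = 0, freshwater = 0.25,
                                      marine = -0.15),
                            scale = c("point/microhabitat" = -0.2,
                                      plot = -0.1, local = 0,
                                      regional = 0.15,
                                      "continental/global" = 0.3)),
  shift = corpus_beta("shift"),
  local_diversity = corpus_beta("local_diversity"))

test_that("noiseless balanced corpus: fixed effects equal raw level means", {
  b <- known_beta()
  sim <- simulate_meta_dataset(n_publications = 60, beta = b, tau = 0,
                               sigma = 0, tau_design = 0, seed = 2)
  eff <- compute_effects(sim$dataset)
  fit <- fit_mixed_model(sim$dataset, "lrr_homogeneity",
                         moderators = c("biome", "scale"), effects = eff)
  expect_true(fit$boundary)  # zero variances sit on the boundary, flagged
  co <- fit$coefficients
  # treatment contrasts against (terrestrial, point/microhabitat)
  expect_equal(co$estimate[co$term == "biomefreshwater"], 0.25,
               tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "biomemarine"], -0.15, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "scaleplot"], 0.1, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "scaleregional"], 0.35, tolerance = 1e-6)
  # balanced noiseless one-factor corpus: EMMs equal arithmetic level means
  b1 <- list(homogeneity = corpus_beta("homogeneity", intercept = -0.1,
                                       biome = c(terrestrial = 0,
                                                 freshwater = 0.25,
                                                 marine = -0.15)),
             shift = corpus_beta("shift"),
             local_diversity = corpus_beta("local_diversity"))
  sim1 <- simulate_meta_dataset(n_publications = 40, beta = b1, tau = 0,
                                sigma = 0, tau_design = 0, seed = 21)
  eff1 <- compute_effects(sim1$dataset)
  emm <- marginal_means(sim1$dataset, "lrr_homogeneity", "biome",
                        effects = eff1)
  df <- merge(sim1$dataset$records, eff1, by = "comparison_id")
  raw <- tapply(df$lrr_homogeneity, df$biome, mean)
  expect_equal(emm$estimate[match(names(raw), emm$level)], as.vector(raw),
               tolerance = 1e-6)
})

test_that("mixed model recovers generative fixed effects within 3 s.e.", {
  b <- known_beta()
  sim <- simulate_meta_dataset(n_publications = 200, beta = b, tau = 0.2,
                               sigma = 0.3, seed = 0)
  eff <- compute_effects(sim$dataset)
  fit <- fit_mixed_model(sim$dataset, "lrr_homogeneity",
                         moderators = c("biome", "scale"), effects = eff)
  co <- fit$coefficients
  truth <- c("(Intercept)" = -0.1 + 0 + (-0.2),
             biomefreshwater = 0.25, biomemarine = -0.15,
             scaleplot = 0.1, scalelocal = 0.2, scaleregional = 0.35,
             "scalecontinental/global" = 0.5)
  for (term in names(truth)) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$se)
  }
  # between-publication variance recovered within 50% relative error
  expect_lt(abs(sqrt(fit$var_publication) - 0.2) / 0.2, 0.5)
})

test_that("Type II Wald statistics follow the quadratic form", {
  # scalar block worked example: (0.5 / 0.25)^2 = 4, p ~ 0.0455
  fake <- structure(list(
    coefficients = data.frame(term = c("(Intercept)", "x"),
                              estimate = c(0, 0.5), se = c(0.1, 0.25)),
    vcov = diag(c(0.01, 0.0625)), assign = c(0L, 1L), terms = "x"),
    class = "mixed_model_result")
  w <- wald_type2(fake, "x")
  expect_equal(w$chi2, 4)
  expect_equal(w$df, 1L)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(w$p, 0.0455, tolerance = 1e-3)
  # zero coefficient block: chi2 = 0, p = 1
  fake$coefficients$estimate[2] <- 0
  w0 <- wald_type2(fake, "x")
  expect_equal(w0$chi2, 0)
  expect_equal(w0$p, 1)
})

test_that("Wald tests agree with car::Anova on a fitted corpus", {
  skip_if_not_installed("car")
  sim <- simulate_meta_dataset(n_publications = 120, beta = known_beta(),
                               tau = 0.15, sigma = 0.25, seed = 3)
  fit <- fit_mixed_model(sim$dataset, "lrr_homogeneity",
                         moderators = c("biome", "scale"))
  ca <- car::Anova(fit$fit, type = "II")
  for (f in c("biome", "scale")) {
    w <- wald_type2(fit, f)
    expect_equal(w$chi2, ca[f, "Chisq"], tolerance = 1e-6)
    expect_equal(w$df, ca[f, "Df"])
  }
})

test_that("marginal means match emmeans and use the stated z quantiles", {
  skip_if_not_installed("emmeans")
  sim <- simulate_meta_dataset(n_publications = 100, beta = known_beta(),
                               tau = 0.15, sigma = 0.25, seed = 4)
  eff <- compute_effects(sim$dataset)
  emm <- marginal_means(sim$dataset, "lrr_homogeneity", "biome",
                        effects = eff)
  df <- merge(sim$dataset$records, eff, by = "comparison_id")
  df$publication_id <- factor(df$publication_id)
  df$design_type <- factor(df$design_type)
  df$biome <- factor(df$biome, levels = ordimeta_levels$biome)
  ref <- lme4::lmer(lrr_homogeneity ~ biome + (1 | publication_id) +
                      (1 | design_type), data = df, REML = TRUE)
  em <- as.data.frame(emmeans::emmeans(ref, "biome", lmer.df = "asymptotic"))
  m <- match(em$biome, emm$level)
  expect_equal(emm$estimate[m], em$emmean, tolerance = 1e-6)
  expect_equal(emm$se[m], em$SE, tolerance = 1e-6)
  # normal-quantile CIs: estimate +/- z * se with z = 1.959964 / 2.575829
  expect_equal(emm$ci95_lo, emm$estimate - 1.959964 * emm$se)
  expect_equal(emm$ci99_hi, emm$estimate + 2.575829 * emm$se)
  expect_true(all(emm$ci99_lo < emm$ci95_lo & emm$ci95_hi < emm$ci99_hi))
})

test_that("regression on local diversity recovers exact and noisy slopes", {
  # known slope with publication intercepts and residual noise: recovered
  # within 3 reported s.e.
  sim <- simulate_meta_dataset(
    n_publications = 150,
    beta = list(homogeneity = corpus_beta("homogeneity", intercept = 0),
                shift = corpus_beta("shift"),
                local_diversity = corpus_beta(
                  "local_diversity", intercept = 0,
                  biome = c(terrestrial = 0.3, freshwater = 0,
                            marine = -0.3))),
    tau = 0.2, sigma = 0.15, tau_design = 0,
    slope_ld = c(homogeneity = 0.5, shift = 0), richness_prob = 1, seed = 6)
  reg <- regress_lrr(sim$dataset, "lrr_homogeneity")
  expect_lt(abs(reg$slope - 0.5), 3 * reg$se)
  # fully deterministic variant: no publication effects at all
  sim2 <- simulate_meta_dataset(
    n_publications = 60,
    beta = list(homogeneity = corpus_beta("homogeneity", intercept = 0.1),
                shift = corpus_beta("shift"),
                local_diversity = corpus_beta("local_diversity",
                                              intercept = -0.2,
                                              biome = c(terrestrial = 0.4,
                                                        freshwater = 0,
                                                        marine = -0.4))),
    tau = 0, sigma = 0, tau_design = 0,
    slope_ld = c(homogeneity = 0.5, shift = -0.3), richness_prob = 1,
    seed = 8)
  reg2 <- regress_lrr(sim2$dataset, "lrr_homogeneity")
  expect_equal(reg2$slope, 0.5, tolerance = 1e-6)
  reg2s <- regress_lrr(sim2$dataset, "lrr_shift")
  expect_equal(reg2s$slope, -0.3, tolerance = 1e-6)
  expect_equal(reg2$wald$df, 1L)
  # subset slopes partition the data and agree in the noiseless case
  expect_true(all(abs(reg2$subsets$slope - 0.5) < 1e-5, na.rm = TRUE))
  biome_rows <- reg2$subsets[reg2$subsets$factor == "biome", ]
  expect_equal(sum(biome_rows$n), reg2$n)
})

test_that("weighted and unweighted fits agree in sign at the defaults", {
  sim <- simulate_meta_dataset(n_publications = 150, beta = known_beta(),
                               tau = 0.2, sigma = 0.3, seed = 9)
  eff <- compute_effects(sim$dataset)
  emm_u <- marginal_means(sim$dataset, "lrr_homogeneity", "scale",
                          effects = eff)
  emm_w <- marginal_means(sim$dataset, "lrr_homogeneity", "scale",
                          weights = "sqrt_n", effects = eff)
  strong <- abs(emm_u$estimate) > emm_u$se  # sign is meaningful
  expect_true(all(sign(emm_u$estimate[strong]) ==
                  sign(emm_w$estimate[strong])))
})

test_that("estimates are invariant to the input row order", {
  sim <- simulate_meta_dataset(n_publications = 50, beta = known_beta(),
                               tau = 0.2, sigma = 0.3, seed = 10)
  ds <- sim$dataset
  set.seed(1)
  perm <- sample(nrow(ds$records))
  ds2 <- meta_dataset(ds$records[perm, ], ds$points, ds$richness,
                      ds$provenance)
  f1 <- fit_mixed_model(ds, "lrr_homogeneity", moderators = "biome")
  f2 <- fit_mixed_model(ds2, "lrr_homogeneity", moderators = "biome")
  expect_lt(max(abs(f1$coefficients$estimate - f2$coefficients$estimate)),
            1e-8)
})
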