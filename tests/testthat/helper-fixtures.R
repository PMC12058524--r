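# shared in-code fixtures

# the four-point configuration whose distance summaries are known by hand:
# D_R = 2, D_I = 1, D_W = 1.5, D_B = (1 + 2*sqrt(2) + sqrt(5))/4
toy_points <- function() rbind(c(0, 0), c(0, 2), c(1, 0), c(1, 1))
toy_labels <- function() c("reference", "reference", "impacted", "impacted")

# one-record dataset around an arbitrary grouped configuration
toy_dataset <- function(points = toy_points(), labels = toy_labels(),
                        richness = NULL, id = "c1") {
  meta_dataset(
    records = data.frame(comparison_id = id, publication_id = "p1",
                         design_type = "experimental", biome = "freshwater",
                         pressure = "pollution", organism = "fish",
                         scale = "local"),
    points = data.frame(comparison_id = id, group = labels,
                        axis1 = points[, 1], axis2 = points[, 2]),
    richness = richness)
}

# brute-force distance summary used as the independent oracle for
# pairwise_group_means: explicit double loops, no vectorization shared
# with the implementation
brute_force_summary <- function(points, labels) {
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  ref <- which(labels == "reference"); imp <- which(labels == "impacted")
  wr <- c(); for (i in ref) for (j in ref) if (i < j)
    wr <- c(wr, euclid(points[i, ], points[j, ]))
  wi <- c(); for (i in imp) for (j in imp) if (i < j)
    wi <- c(wi, euclid(points[i, ], points[j, ]))
  bt <- c(); for (i in ref) for (j in imp)
    bt <- c(bt, euclid(points[i, ], points[j, ]))
  list(D_R_bar = mean(wr), D_I_bar = mean(wi), D_B_bar = mean(bt),
       D_W_bar = sum(c(wr, wi)) / (length(wr) + length(wi)))
}

# random grouped configuration for property tests
random_config <- function(n_ref, n_imp) {
  list(points = matrix(stats::rnorm((n_ref + n_imp) * 2), ncol = 2),
       labels = c(rep("reference", n_ref), rep("impacted", n_imp)))
}

# 2D rigid motion + uniform scaling
similarity_transform <- function(points, angle = 0, scale = 1,
                                 shift = c(0, 0), reflect = FALSE) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  if (reflect) r <- r %*% diag(c(-1, 1))
  sweep(points %*% t(r) * scale, 2, shift, "+")
}
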