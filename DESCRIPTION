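Package: ordimeta
Title: Meta-Analysis of Beta-Diversity Change from Ordination-Derived Effect Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for control-impact meta-analyses of community change built on
    two-dimensional ordination coordinates (PCoA or NMDS). Computes three
    log-response-ratio effect sizes per comparison (community homogeneity,
    compositional shift, and local diversity), synthesises them across studies
    with linear mixed models (crossed random intercepts for publication and
    study design, Type II Wald chi-square tests, estimated marginal means with
    dual confidence intervals, and an optional square-root-of-sample-size
    weighted variant), screens for publication bias (funnel asymmetry,
    Rosenthal fail-safe N, p-curve), and probes the robustness of the effect
    sizes to extra groups in the source ordination. A synthetic-data generator
    produces grouped point clouds, community matrices, digitization artifacts,
    and whole hierarchical meta-corpora with known ground truth so every stage
    of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    lme4
Suggests:
    testthat (>= 3.0.0),
    MASS,
    emmeans,
    car,
    metafor,
    ape,
    jsonlite
Config/testthat/edition: 3
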