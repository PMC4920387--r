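Package: befpart
Title: Diversity-Effect Partitioning and Trait-Based Inference for
    Biodiversity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for grass-forb biodiversity experiments
    crossing species richness with light (shading) and nutrient
    (fertilization) availability. Computes relative yields, relative yield
    totals and transgressive overyielding, the tripartite partition of net
    diversity effects into trait-independent complementarity,
    trait-dependent complementarity and dominance effects (with the
    Loreau-Hector additive partition as a cross-check), community-weighted
    mean traits and single-trait Rao quadratic entropy, sequential (type I)
    mixed-model ANOVA with Satterthwaite, Kenward-Roger or design-based
    re-randomization inference, one-sample tests against reference values,
    post-hoc least-squares-mean differences, and all-subsets AIC multimodel
    inference with full model averaging. Includes a synthetic-data
    generator that reproduces the experimental design (8 blocks x 12
    plots, two 4-species pools, 2x2 shade x fertilization) with known
    ground-truth diversity effects so every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    yaml
Suggests:
    pbkrtest,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
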