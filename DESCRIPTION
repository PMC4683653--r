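Package: gxdmod
Title: Genotype-by-Diet Variance Partitioning and Modular Endophenotype
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting genotype, diet, and genotype-by-diet
    effects on molecular endophenotypes (transcript and metabolite
    profiles) measured in factorial line-by-diet designs.  Provides
    per-feature two-way ANOVA with Benjamini-Hochberg false-discovery
    control, correlation-based module detection by adaptive-sharpening
    modularity maximization, module summarization by the first principal
    component and its mapping to gross phenotypes, feature-trait
    correlation profiling per diet, forward stepwise regression with BIC
    for minimal predictor sets, and second-order "co-correlation"
    statistics that test conservation of trait-correlate profiles across
    traits, diets, and measurement platforms.  A synthetic factorial data
    generator plants variance components, correlated-feature modules, and
    diet-specific trait loadings so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
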