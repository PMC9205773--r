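Package: phenoscape
Title: Neuroanatomical Endophenotype Analysis for Mouse Models of Immune
    Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links structure-wise brain volumes from mutant mouse cohorts to
    behavioural phenotype annotations. Provides per-structure frequentist
    linear models with partial F-tests and false-discovery-rate control, a
    Bayesian hierarchical model of standardised volumes with global and
    structure-specific effects of sex, strain and their interaction, posterior
    effect-size (Cohen's d) and eta-squared distributions, closed-form
    Gaussian Hellinger distances between strain endophenotypes with a
    label-permutation test, preferential spatial gene-expression fold-change
    scoring with hypergeometric gene-set enrichment, and k-means clustering of
    developmental expression trajectories with elbow-based model selection.
    Includes a seeded synthetic-data generator that emulates the cohort,
    anatomy and expression-atlas inputs, so every stage can be exercised and
    calibrated without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    igraph,
    jsonlite,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
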