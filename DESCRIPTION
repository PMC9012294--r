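Package: immunotraj
Title: Paired Pre/Post-Treatment Peripheral Immune Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies adaptive immune activation in paired pre-/post-treatment
    patient cohorts from peripheral blood. Implements T cell receptor (TCR)
    repertoire analysis (Simpson diversity index family, diversity log fold
    change, top-clone expansion profiles from AIRR Rearrangement tables),
    single-cell expression summaries (counts-per-10k log normalization, cluster
    proportions and their log fold change, per-cluster pseudobulk gene log fold
    change and a mean-absolute-logFC "disturbance" score, pathway mean-expression
    scoring, marker-based cluster annotation), preranked gene set enrichment with
    a gene-permutation null, and exact-permutation Spearman correlation linking
    dendritic-cell activation to clonal expansion. A seeded synthetic cohort
    generator with planted effects (Zipf clone-size law, negative-binomial
    counts, interferon-module upregulation, coupled responder strength) supports
    parameter-recovery testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
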