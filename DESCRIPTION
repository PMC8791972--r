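Package: bmiomics
Title: Biphasic BMI-Dependence Analysis for Myocardial Transcriptomics and Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects u- and n-shaped relationships between omics features and a
    continuous covariate (body mass index) with a two-segment breakpoint
    statistic, derives data-driven covariate groups from the breakpoint
    distribution, and runs moderated differential expression, competitive
    gene-set tests with inter-gene correlation adjustment, weighted
    correlation-network module and eigengene analysis, PLS-DA metabolite
    contrasts with VIP scoring, and two-block latent-variable
    transcript-metabolite association networks. Includes a seeded synthetic
    data generator emulating the statistical structure of a myocardial
    biopsy cohort so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    mixOmics
Config/testthat/edition: 3
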