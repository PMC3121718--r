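Package: txanchor
Title: DNA Damage-Anchored Differential Expression for Two-Site Factorial
    Microarray Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for transcriptomic studies that anchor gene expression to a
    measured DNA-damage phenotype. Implements RMA-style preprocessing
    (background correction, quantile normalization, median-polish
    summarization), per-probeset factorial linear models with a two-laboratory
    replication-consistency filter, FDR- and fold-change-gated differential
    expression calls, phenotype anchoring by Spearman correlation of expression
    with O6-methylguanine lesion burdens, hypergeometric/EASE gene-set
    overrepresentation, promoter transcription-factor binding-site (TRE)
    interaction matrices with prevalence filtering and enrichment tests,
    rank-based (Wilcoxon scores) comparison of adduct burdens between
    genotypes, and a truth-labelled synthetic data generator emulating a
    2 site x 2 genotype x 2 treatment x 4 timepoint design with matched
    lesion time-courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
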