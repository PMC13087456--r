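Package: minorsplice
Title: Minor Spliceosome Disease Genomics: Rare-Variant Discovery, U12
    Intron Retention, Co-Expression Modules, and Immune Deconvolution
Version: 0.1.0
Authors@R:
    person("minorsplice", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Analysis toolkit for recessive disorders of the minor
    spliceosome snRNAs. Provides ultra-rare bi-allelic variant
    prioritization across coding and non-coding genes with candidate-panel
    screening, per-intron percent-spliced-in (PSI) quantification and
    case/control differential intron-retention testing against a
    U2/U12 intron annotation, weighted co-expression network analysis
    (soft thresholding, topological overlap, module detection, eigengenes,
    module-trait correlation, gene-set enrichment), reference-based
    cell-composition deconvolution of methylation or expression profiles by
    simplex-constrained least squares, and clinical cohort summary
    statistics including snRNA transcript-to-genome coordinate anchors.
    A synthetic-data module generates every input format with planted
    ground truth so the full pipeline is testable without controlled-access
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
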