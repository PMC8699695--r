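Package: sdconcord
Title: Cross-Species Transcriptome Concordance and Circadian Period Analysis
    for Short-Photoperiod Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether differentially expressed genes from a mouse
    model are concordantly dysregulated in human autism-spectrum-disorder (ASD)
    expression cohorts, and to characterise the circadian phenotype of the
    model from wheel-running records. Provides per-gene linear-model screening
    with an age-by-diagnosis interaction selection rule, fold-change and t-test
    DEG calling, cohort balancing, mouse-to-human homolog mapping with
    multi-cohort Venn tallies, learning-vector-quantization classification of
    ADI-R severity class with per-class ROC-based gene importance, a Morlet
    continuous-wavelet periodogram for binned activity records, formula-defined
    behavioural and morphological summary metrics, and a seeded synthetic-data
    generator for every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
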