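Package: panelforge
Title: Construction and Quality Control of Population Allele Frequency Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cohort-level allele frequency reference panels from
    per-sample variant call files. Implements chunked joint genotype
    aggregation with overlap reconciliation, sex-aware ploidy handling on the
    X chromosome under two pseudoautosomal-region conventions, circular
    mitochondrial genome calling via two shifted linearizations, relatedness
    (IBD/PIHAT) and karyotype sample quality control, multiallelic allele
    count/number/frequency computation, genotype concordance against SNP
    array data, cross-panel allele frequency comparison, transition to
    transversion ratios, genome accessibility depth tracks, and the
    population-structure workflow (Hardy-Weinberg exact test, variant
    filtering, LD pruning, PCA). A seeded synthetic cohort generator
    reproduces the statistical structure the pipeline assumes so every stage
    is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
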