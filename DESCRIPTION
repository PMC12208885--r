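Package: leukotrace
Title: Tracing Leukemia Evolution in Single-Cell and Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of the bespoke computational
    procedures used to trace B-cell precursor leukemia evolution across
    single-cell and genomic assays: cell-hashing demultiplexing with
    ambient-background standardization, single-cell quality control and
    per-cluster differential-abundance testing, transcription-factor regulon
    discovery with train-test stability and cell-type discriminability
    filtering, tumor-normal somatic variant filter batteries with recurrence
    summaries, and recombination-signal-sequence motif annotation of
    structural-variant breakends. Seeded synthetic-data generators provide
    inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    Biostrings,
    BiocGenerics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
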