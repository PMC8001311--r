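Package: uceditr
Title: Detection and Chromatogram Validation of U-to-C RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate U-to-C RNA-editing sites in
    nuclear transcripts from RNA-seq versus genome differences, and for
    confirming them by Sanger chromatogram dual-peak analysis. Provides
    read quality-control filters, a minimal ungapped read placer, per-site
    pileup construction, strand-aware classification of RNA-DNA differences
    into the twelve transcript-level conversion types, SNP and polymorphism
    filters, UTR/CDS feature annotation, peak-area editing-efficiency
    quantification from four-channel trace data, and a seeded synthetic-data
    generator with truth tables so the whole workflow can be exercised and
    evaluated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
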