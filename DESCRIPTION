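Package: modscreen
Title: Intragenic Suppressor Identification from Whole-Genome-Sequenced
    Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for forward-genetics modifier screens in
    C. elegans that were whole-genome sequenced without backcrossing.
    Filters per-strain variant calls by depth, allele fraction, gene
    context and parental de novo status; annotates coding effects with
    simplified HGVS c./p. nomenclature from first principles; interprets
    revertants versus wildtype contamination using mutagen mutational
    spectra; summarises screen saturation through recurrent positions and
    codons; computes hatching-rate and population-assay statistics with
    product-limit survival curves; and compares Sanger versus WGS
    screening costs.  Ships a synthetic screen generator emulating EMS and
    ENU mutagenesis so every stage is testable with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    survival,
    graphics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
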