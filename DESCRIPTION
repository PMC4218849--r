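Package: igphase
Title: Immunoglobulin Repertoire Sequencing with Subclass Phasing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes four-read Illumina-style amplicon runs in which the
    first index read is repurposed as a 12-nucleotide IgG subclass
    identifier. Demultiplexes clusters by the second (sample) index, calls
    the IgG subclass (or the pooled light-chain/other-isotype category) from
    the identifier read plus one discriminator base at the start of read 2,
    merges paired-end variable-region reads by quality-aware overlap
    consensus, and reports subclass frequencies. Includes a ground-truthed
    run simulator so the whole pipeline is testable without sequencing data,
    and a scheme deriver that extracts subclass identifiers from CH1
    constant-region references.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
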