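Package: mirseeker
Title: Small RNA miRNA Discovery, Hairpin Screening and Degradome Target Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of a plant small-RNA miRNA discovery
    pipeline: adapter trimming and contaminant filtering with an exact removal
    ledger, exact-match genome anchoring, classification of reads into known,
    conserved and novel miRNA candidates, five-criterion miRNA/miRNA* hairpin
    screening with MFE/AMFE/MFEI thermodynamic filtering (MFEI > 0.8),
    reads-per-million fold-change calling between two libraries, 2^-ddCt
    qRT-PCR quantification, and degradome (PARE) t-plot based target calling
    with CleaveLand-style abundance categories. Includes a synthetic-data
    generator that plants hairpins, library abundances, contaminants and
    cleavage sites with machine-readable ground truth so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
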