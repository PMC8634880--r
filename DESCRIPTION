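Package: cleavemap
Title: Mapping Endoribonuclease Cleavage Sites from Positional Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the recognition sequence of sequence-specific
    single-stranded RNA endoribonucleases (MazF-family toxins) from
    positional sequencing coverage of digested substrate RNAs. Implements
    the relative coverage increase (RCI) statistic with zero-coverage
    pseudocounting, a per-substrate median-coverage filter, fixed-threshold
    site calling with 11-nt window extraction, top-k ranking, and a
    position weight matrix / information-content / IUPAC-consensus motif
    model of the called windows. Includes a seeded simulator of the
    cleavage-fragmentation-sequencing process for parameter-recovery
    testing, IUPAC motif scanning of coding sequences, and pairwise and
    multiple-alignment conservation displays for the enzyme proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
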