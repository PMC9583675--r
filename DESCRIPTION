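Package: vd2rep
Title: Public and Private Vdelta2 T Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of human Vdelta2+ T cell receptor (TRD) repertoires
    across age groups: germline junction re-annotation and N-insertion
    counting from CDR3 nucleotide sequences, public/private clonotype
    classification, synonymous-transcript (convergent recombination)
    multiplicity, a BLOSUM62-penalty CDR3 distance with a pluggable 2-D
    embedding, clonal expansion-status scoring, and Games-Howell group
    comparisons. Includes a V(D)J rearrangement simulator for TRDV2
    repertoire cohorts with age-dependent J usage and TdT activity, used
    as ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
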