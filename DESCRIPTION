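Package: hsfminer
Title: Gene-Family Mining and Annotation for Plant Heat Shock Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for genome-mining heat shock transcription
    factor (Hsf) families: position-specific scoring of the ~100-residue DNA-binding
    domain, heptad-repeat delimitation of the HR-A/B oligomerization region,
    classification into classes A/B/C by the length of the insertion between HR-A and
    HR-B (21, 0 or 7 residues), rule-based annotation of NLS, NES and AHA motifs,
    duplicated-gene-pair calling under explicit coverage and similarity criteria from
    Needleman-Wunsch global alignment, neighbor-joining phylogenies with
    Poisson-corrected pairwise-deletion distances and bootstrap support, and
    physicochemical (molecular weight, isoelectric point) and qPCR delta-delta-Ct
    expression summaries. A synthetic-family generator with full ground truth makes
    every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
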