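Package: codonbias
Title: Codon Usage Bias Analysis of Gene Families
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for codon usage bias (CUB) analysis of coding-sequence
    (CDS) sets: codon counting and composition metrics (GC1/GC2/GC3, GC3s,
    silent third-position base frequencies), the classical CUB indices
    (RSCU, Wright's effective number of codons, CAI, CBI, Fop), protein
    level metrics (GRAVY, aromaticity, isoelectric point, molecular
    weight), mutation-versus-selection diagnostics (ENc-GC3s plot with the
    expected curve, parity rule 2 bias, neutrality regression,
    expression correlation), optimal codon determination from
    ENc-extreme gene pools, RSCU-based PCA and hierarchical clustering,
    and neighbor-joining phylogenetics on p-distances with bootstrap
    support. A synthetic CDS generator with planted codon preferences
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
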