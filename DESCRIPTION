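Package: vestige
Title: Inference of Gene Inactivation from Comparative Genomic Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for detecting pseudogenization (gene inactivation) across
    a clade of species. Reference exons from an annotated gene model are
    mapped onto orthologous genomic loci with an affine-gap glocal aligner;
    ORF-disrupting lesions (frameshift indels, premature stop codons,
    non-canonical splice-site dinucleotides, whole-exon deletions) are called
    and left-normalized; per-species coding verdicts are assigned; lesions
    shared across species are placed on a species tree by Dollo parsimony;
    lesions are validated against genomic reads and RNA-seq reads are
    classified by splicing maturity. A synthetic clade simulator with a
    machine-readable truth table makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
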