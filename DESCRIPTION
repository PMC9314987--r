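Package: asmpair
Title: Assembly-to-Assembly Structural Variant and Segmental Duplication Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two related genome assemblies end to end: simulates
    assembly pairs with planted structural variants, segmental duplications
    and assembly gaps; aligns them with a unique-anchor chaining aligner;
    builds a one-to-one synteny map with gap-filling and gapless-length
    statistics; classifies intra-chromosomal structural variants (deletions,
    insertions, duplications, inversions) with length and continuity
    filters; detects inter-chromosomal segmental duplications from
    many-to-one alignments, resolves parental and derived copies and
    categorizes duplication direction between the X chromosome and
    autosomes; and tests the X chromosome as an outlier of the
    autosome count-versus-length regression with effective-population-size
    adjusted deficiency and excess rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    rtracklayer,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
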