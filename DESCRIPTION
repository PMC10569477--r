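Package: degenmix
Title: Degenerate Primer Mix Design and In-Silico PCR Validation for
    Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design equimolar pools ("mixes") of degenerate PCR primers from
    an alignment of marker-gene orthologs, and validate them in silico.
    From a nucleotide alignment the package locates conserved, gap-free
    candidate binding windows under explicit length, melting-temperature,
    GC-content and secondary-structure guidelines; partitions the target
    panel into groups each coverable by one degenerate oligo carrying at
    most four non-consecutive IUPAC ambiguity codes; optionally relaxes a
    variant by one extra degeneracy to widen coverage; predicts PCR
    products of the resulting mixes on template sequences; and assesses
    the amplified fragment as a phylogenetic marker with distance-based
    trees.  A deterministic simulator generates gene families with planted
    conserved blocks so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
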