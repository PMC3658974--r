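Package: cuproclass
Title: Classification and Evolutionary Analysis of Type-3 Copper Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects binuclear copper-binding sites (the paired Cu(A) and
    Cu(B) histidine triads of tyrosinases, catechol oxidases and
    hemocyanins) with a configurable motif grammar, predicts domain
    architecture (signal peptide, transmembrane segment, cysteine-rich
    region) from hydropathy heuristics, assigns proteins to the secreted
    (alpha), cytosolic (beta) and membrane-bound (gamma) subclasses,
    looks up compatible functional classes from active-site features,
    builds motif-anchored alignments and neighbor-joining trees with
    bootstrap support and midpoint rooting, detects tandem gene clusters
    from genomic coordinates, and reconstructs subclass losses and
    lineage-specific expansions on a species tree under a Dollo model.
    Ships a synthetic census generator that emulates the structure of a
    published 179-protein survey so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
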