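Package: propsel
Title: Detection of Selection on Amino Acid Physicochemical Properties Along Phylogenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects positive-destabilizing selection on amino acid
    physicochemical properties in protein-coding genes along a phylogeny.
    Nonsynonymous replacements are inferred by codon-state parsimony, binned
    into eight magnitude categories of property change, and compared with the
    expectation under random single-nucleotide amino acid replacement via
    z-scores; includes a whole-protein sum-of-z test, cross-clade shared-site
    comparison tables, and a codon evolution simulator with planted
    destabilizing bias for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
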