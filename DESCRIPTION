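Package: plastdeg
Title: Comparative Analysis of Plastome Structure and Gene Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of plastid genome (plastome)
    degradation in photosynthetic and hemiparasitic plants. Detects the
    quadripartite structure (LSC/IRb/SSC/IRa) of circular plastomes from raw
    sequence, classifies inverted-repeat boundary architectures, calls a
    four-state functionality code for protein-coding genes (functional,
    premature stop, truncated, lost), computes relative synonymous codon
    usage and GC statistics, runs rank-based association tests, and
    reconstructs the history of gene functional loss on a rooted phylogeny
    by Dollo parsimony and by an equal-rates Markov (Mk) likelihood model
    with marginal ancestral states. Includes generators for fully annotated
    synthetic plastomes and discrete characters with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
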