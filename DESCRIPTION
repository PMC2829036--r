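Package: ecrmotifs
Title: Microdomain Annotation and Structural Typing of Ecdysone Receptor
    Isoform-Specific Regions
Version: 0.1.0
Authors@R:
    person("EcR", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of the N-terminal
    isoform-specific regions of insect ecdysone receptor (EcR) A and B1
    isoforms. Detects short conserved microdomains (SUMOylation motif,
    monopartite NLS, (D/E)(D/E)W residues, A-box, S-rich and DL-rich
    compositional motifs, the holometabolan (K/R)RRW motif and related
    N-terminal signatures) with a degenerate consensus-pattern grammar and
    compositional-window rules, classifies regions into the twelve
    published structural architectures (five A types, seven B1 types),
    builds degenerate consensus strings and information-content profiles
    from alignments, reconstructs motif gain and loss over an insect
    cladogram by Fitch parsimony, and generates ground-truthed synthetic
    exemplar sequences for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
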