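Package: amyphylo
Title: Gene-Family Phylogenetics and Amyloidogenic-Potential Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of a multi-clade gene family
    such as the amyloid-beta precursor protein (APP/APLP) family: iterative
    homolog collection by stringent local-alignment similarity closure,
    maximum-parsimony tree search with Fitch/Hartigan scoring, enumeration of
    most-parsimonious reconstructions and calling of unambiguous
    synapomorphies, per-domain synapomorphy frequency profiling, and a
    beta-pairing energy model with a k-of-n consensus predictor for
    classifying amyloidogenic potential of beta-A4-homologous regions
    projected onto a tree.  Includes a sequence-evolution simulator with
    planted clade-diagnostic substitutions and planted aggregation-prone
    segments so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
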