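Package: paleofit
Title: Stratigraphic Congruence, Ancestral Areas and Parsimony Fit for
    Fossil Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for confronting fossil phylogenies with stratigraphic and
    biogeographic data. Computes ghost-lineage durations, the minimum implied
    gap (MIG) and the gap excess ratio (GER) for rooted trees against
    first-appearance data, compares the stratigraphic fit of competing
    topologies, propagates geographic-area probabilities from tips to root on
    consensus trees, and scores character-taxon matrices on trees (tree
    length, per-character and ensemble consistency/retention/homoplasy
    indices, unambiguous synapomorphies) under ordered and unordered
    optimization. Includes seeded simulators for trees, stratigraphic ranges,
    discrete characters and tip areas, and a worked marine-turtle example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
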