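Package: ilsrad
Title: Disentangling Hybrid Speciation, Gene Flow, and Incomplete
    Lineage Sorting in Rapid Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether phylogenetic discordance among
    closely related lineages is caused by hybrid speciation, gene flow,
    or incomplete lineage sorting (ILS), and for localizing ILS tracts
    and ILS-affected genes along a genome. Includes a multispecies
    coalescent simulator on species networks with introgression pulses,
    window-based gene-tree building and topology-frequency tests,
    ABBA-BABA D statistics with the weighted block jackknife, the
    five-taxon D_FOIL direction statistics, an internal-branch-length
    exponential mixture model compared by BIC, a divergence-time
    ordering test, a four-state coalescent hidden Markov model with
    posterior decoding and segment statistics, and CDS-coverage
    filtering of ILS genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
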