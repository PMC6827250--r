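Package: alginseq
Title: Alginate Oligosaccharide Sequencing and Lyase Digestion Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for sequencing unsaturated alginate oligosaccharides from
    exolytic truncation series combined with integrated 1H NMR signal areas,
    and for modelling the enzymatic depolymerization of alginate. Provides
    domain types for M/G uronate chains and size-class mixtures, exact
    monoisotopic mass and negative-mode [M-H]- m/z calculation for
    unsaturated and saturated oligouronates, a stochastic (Gillespie)
    simulator of endolytic and exolytic alginate lyase digestion with
    configurable bond-pair cleavage preferences and substrate-size-dependent
    exolytic rates, a forward model of position-diagnostic NMR readouts,
    reconstruction of mixture composition from positional marginals under
    positional independence, endo/exo co-digestion synergy quantification,
    and seeded synthetic-data generators (block-structured chains, noisy
    readout series, gel-filtration-style peak tables) so the whole pipeline
    is testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
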