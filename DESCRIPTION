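Package: gillsym
Title: Symbiont Community Assembly Analysis for Shipworm Gill Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the assembly of intracellular bacterial
    symbiont communities in shipworm (Teredinidae) gill metagenomes.
    Converts per-specimen symbiont read counts into relative abundances
    and presence/absence profiles; tests observed symbiont co-occurrence
    patterns against a richness-preserving Monte Carlo null model, with
    exact Poisson-binomial tests for never-observed species pairs and an
    exact guarantee probability for nitrogen-fixing symbionts; predicts
    nitrogen-fixation capability from nif gene-class content; constrains
    core CAZyme and nif gene sets by intersecting the gene complements of
    minimal sufficient communities; delimits symbiont species from
    pairwise genome-wide average nucleotide identity records; and
    simulates synthetic datasets with known planted structure so that
    every stage can be validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
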