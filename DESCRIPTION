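Package: xenolog
Title: Detection, Dating and Characterisation of Horizontally Transferred
    Genes in Grass Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering fungus-originated genes in grass genomes
    and transcriptomes, dating the transfer events on calibrated species
    trees, and characterising the transferred genes.  Implements read
    collapsing and a seeded local-alignment screen with Karlin-Altschul
    E-values, rule-based triage of similarity hits, Dollo (single-gain)
    dating of gene acquisitions on dated phylogenies, Nei-Gojobori Ka/Ks
    estimation with Jukes-Cantor correction and divergence-age-normalised
    rates, codon usage profiling including the termination signal,
    exact-match read counting with counts-per-million normalisation, and
    in-silico PCR.  A codon-level sequence-evolution simulator plants
    horizontal gene transfer events at known times so that the whole
    pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
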