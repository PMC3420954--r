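Package: eyespots
Title: Phylogenetic Origins and Developmental Timing of Butterfly Eyespots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analyses of the origin of nymphalid butterfly eyespots
    and their underlying gene-regulatory network. Implements an asymmetric
    two-rate continuous-time Markov model for binary traits on time-calibrated
    phylogenies (closed-form transition probabilities, pruning likelihood with
    optional fixed ancestral node states, maximum-likelihood rate estimation,
    and marginal ancestral-state reconstruction), likelihood comparison of
    competing trait-origin hypotheses under a two-log-unit decision rule, a
    mixed-bootstrap test for differences in the temporal onset of gene
    expression based on areas under logistic curves, uncorrected-distance
    molecular-clock dating of species pairs, a regression test relating
    gene-network complexity to eyespot ring complexity, and seeded synthetic
    data generators for every input so the full pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
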