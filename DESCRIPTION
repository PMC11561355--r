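Package: stygodec
Title: Time-Stratified Ancestral Range Estimation and Constrained
    Habitat Evolution for Subterranean Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Likelihood machinery for historical biogeography and habitat
    evolution of groundwater-adapted lineages. Implements the
    dispersal-extinction-cladogenesis (DEC) family of ancestral range
    models with founder-event speciation (+J), time-stratified dispersal
    multiplier matrices, and the w multiplier exponent; maximum-likelihood
    fitting and AICc-based comparison of biogeographic hypotheses;
    constrained all-rates-different Markov models for habitat and altitude
    states with palaeovalley-structured transition masks; stochastic
    character mapping with colonization and subterranean-speciation
    counting; a scanner for frameshift and premature-stop lesions in
    aligned vision-gene coding sequences; and seed-reproducible simulators
    for dated trees, geographic ranges, discrete traits and lesioned
    coding alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools
Config/testthat/edition: 3
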