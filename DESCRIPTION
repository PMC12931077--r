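Package: kvmix
Title: Binomial Heteromer Mixture Models for Kv10 Channel Gating and
    Optical Resting-Potential Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of heteromeric voltage-gated
    potassium (Kv10.1/Kv10.2) channel gating. Implements a
    Hodgkin-Huxley/Boltzmann description of steady-state activation, a
    binomial subunit-stoichiometry mixture model for wild-type/mutant
    coexpression current-voltage relationships, a binomially weighted
    multi-exponential model of tail-current deactivation with global
    fitting across a voltage family, and a ratiometric genetically
    encoded voltage indicator pipeline (nucleus segmentation,
    single-cell fluorescence extraction, adaptive background
    correction, expression gating, gramicidin one-point calibration,
    per-dish resting-voltage summaries). Seeded synthetic-data
    generators emulate patch-clamp trace families and single-cell
    imaging populations for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
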