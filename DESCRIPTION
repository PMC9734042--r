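Package: neuroflux
Title: Compartmental Modeling of Brain Energy Metabolism from FDG-PET and
    Dynamic 13C-MRS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative neuroenergetics in the rodent brain:
    two-tissue compartment kinetic modeling of 18FDG-PET time-activity
    curves (k1-k4, SUV, CMRglc), positional 13C fractional-enrichment
    labeling models of brain glucose oxidation in one-compartment and
    pseudo three-compartment (excitatory neuron, inhibitory neuron, glia)
    configurations, mass-balance derivation of neurotransmitter cycling
    and GABA-shunt fluxes with relative allostatic-load scores, bounded
    least-squares flux estimation with Monte-Carlo uncertainty, NMR
    overlap algebra for NADH/NAD+ quantification, and the accompanying
    cohort statistics (composite behavioral z-scores, omnibus permutation
    tests, Pearson correlation panels and ROC marker assessment).
    Includes a seeded synthetic-cohort generator so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
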