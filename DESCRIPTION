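Package: swbniche
Title: Isotopic Niche Metrics for Benthic Invertebrates in Small Water Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and compares the isotopic niches of benthic
    invertebrate communities in agricultural ponds and ditches from paired
    carbon and nitrogen stable isotope measurements. Provides delta-notation
    utilities and mean-offset corrections for fertilizer-driven d15N
    enrichment and maize (C4) d13C signals, the six Layman community
    metrics, Bayesian bivariate-normal niche models with standard ellipse
    areas (SEA.B, SEAc) and highest-density posterior summaries,
    maximum-likelihood ellipse overlap, toxic-unit scoring of pesticide
    residues against EC50/LC50 endpoints, and a BIOENV/dbRDA linkage of
    per-site niche metrics to environmental stressors, together with a
    synthetic-data generator that emulates the field study design for
    closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
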