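Package: pieQuant
Title: Quantitative Analysis of Germline Protein Enrichment in the Early C. elegans Embryo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how a maternally deposited germline determinant
    (PIE-1::GFP) becomes enriched in the C. elegans P lineage. Implements
    absolute intracellular concentration estimation from bath-calibrated
    confocal images (flat-field, camera-background and autofluorescence
    correction), blastomere volumetrics from labelled membrane-marker
    z-stacks, a mass-balance model of asymmetric partitioning at cell
    division (segregation fractions, predicted maternally inherited
    concentrations, synthesis decomposition), FRAP-style time-series
    analysis of lineage-restricted synthesis, and two-stage RNAi-screen
    hit-calling statistics. A synthetic-scene generator with full ground
    truth (optics model with uneven illumination, Poisson and Gaussian
    noise, divisions, photobleaching, synthesis and degradation) supports
    end-to-end validation of every estimator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
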