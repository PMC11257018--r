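Package: pursuitgwas
Title: Smooth-Pursuit Oculomotor Phenotyping and Quantitative-Trait
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phenotyping smooth-pursuit eye movements from 1 kHz
    infrared oculography traces (calibration regression, blink rejection,
    acceleration-threshold saccade detection and classification, RMSE and
    pursuit gain) and for quantitative-trait genome-wide association on the
    resulting measures: genotype quality control, Hardy-Weinberg exact
    tests, genotype principal components, additive linear-model
    association, genomic-control diagnostics, identity-by-state clustering
    with within-cluster max-T permutation correction, LD-based clumping,
    and noncentral-F power analysis.  A synthetic-data module generates
    target waveforms, annotated eye-movement sessions, and genotype and
    phenotype cohorts with known ground truth so that every stage of the
    pipeline can be tested end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
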