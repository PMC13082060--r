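Package: deep3pm
Title: Photon Budgets, Transient Detectability and Trace Analysis for Deep Three-Photon Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative models and analysis tools for deep-tissue three-photon
    fluorescence microscopy. Implements the excitation-side photon budget
    (attenuation through layered tissue with piecewise-constant effective
    attenuation lengths, depth-dependent optimal pulse energy and laser
    repetition rate), the collection-side geometry model (diffuse emission
    spread and field-of-view penalty), the d-prime signal-detection statistic
    for single calcium transients under a Poisson photon budget with a
    Monte-Carlo matched-filter oracle, signal-to-background-ratio
    quantification on image stacks with depth-limit and attenuation-length
    estimation, and the activity-trace extraction pipeline (ROI integration,
    Hamming low-pass, lower-quantile baseline, dF/F, 3-D median video filter).
    Seeded synthetic-data generators produce image stacks and activity movies
    with the statistical structure the analysis assumes, so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
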