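Package: wolfalps
Title: Transboundary Monitoring of an Alpine Wolf Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools implementing a transboundary monitoring standard for a
    recolonising Alpine wolf population. Classifies signs of presence into
    validation categories (C1 hard evidence, C2 confirmed, C3 unconfirmed),
    confirms 10x10 km occurrence grid cells and the area of occurrence within
    the Alpine range, resolves reproductive units (packs and pairs) across
    national borders without double counting, and estimates the annual
    population growth rate with a Bayesian hierarchical state-space model
    (exponential growth with lognormal process error and a gamma-Poisson
    observation model, fitted with JAGS). A spatially explicit recolonisation
    simulator with imperfect detection and genotyping provides ground-truthed
    synthetic datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    mgcv,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
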