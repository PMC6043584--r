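Package: dfcstates
Title: Stationary and Dynamic Functional Connectivity Under Graded Anesthesia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dose-graded resting-state fMRI cohorts with
    stationary and dynamic functional-connectivity (FC) methods. Provides a
    seeded generator of modular, state-switching regional BOLD time series with
    a dose covariate that attenuates homotopic (left/right mirror) correlations
    and shifts latent-state occupancy toward a spatially unstructured state;
    FSL-style high-pass filtering, variance normalisation and dual regression;
    full and ridge-regularised partial correlation networks with Fisher
    z-transform, homotopic-edge extraction, max-statistic permutation tests,
    one-way ANOVA across doses, Benjamini-Hochberg FDR and dendrogram
    clustering; and a dynamic-FC pipeline of sliding-window correlations,
    sparse dictionary learning of connectivity states with Hungarian fold
    matching and consensus, least-squares back-fitting of state weights,
    variance-explained accounting and group statistics on state weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, ape, RNifti
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
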