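Package: spenfmri
Title: Spatiotemporal-Encoded MRI Simulation and Olfactory fMRI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of single-shot functional MRI
    of the rodent olfactory bulb under strong field inhomogeneity. Provides a
    digital olfactory-bulb phantom with air-interface-like off-resonance
    fields; forward simulation of gradient-echo and spin-echo EPI and of
    fully- and partially-refocused spatiotemporally encoded (SPEN)
    acquisitions; Fourier and regularized super-resolution reconstruction;
    block-design BOLD experiment simulation with odor-, nostril- and
    concentration-dependent activation; and the matching analysis chain (ROI
    time courses, Gaussian smoothing, first-level GLM t-maps, second-level
    t-tests and one-way ANOVA, max-statistic permutation inference, and
    quality-control screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
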