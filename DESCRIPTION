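Package: upmclock
Title: Universal PaceMaker Versus Molecular Clock Models of Epigenetic Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares two likelihood-based models of DNA-methylation
    aging. Under the molecular clock (MC) each CpG site drifts linearly with
    chronological age at a site-specific rate; the fit is a closed-form linear
    least squares. Under the universal pacemaker (UPM) all sites within an
    individual may speed up or slow down together, which is equivalent to
    replacing chronological age with an inferred per-individual "epigenetic
    age"; the fit searches only the space of individual ages, solving the
    per-site parameters analytically at each candidate. The two models are
    compared with a likelihood-ratio test. Includes a synthetic-data
    generator for pacemaker-perturbed methylation trajectories, a
    replicate-based power study of pacemaker detection, and reporting
    utilities for rate ratios, epigenetic-age ratios and top-variance site
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
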