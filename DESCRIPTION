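Package: cudosim
Title: Preclinical-to-Clinical Dosimetry for Copper-64 ImmunoPET Tracers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts human organ absorbed doses, effective dose, the
    dose-limiting organ and maximum administrable activity for a
    radiolabeled antibody (e.g. 64Cu-pembrolizumab) from mouse
    biodistribution data. Converts gamma-counter or ROI measurements to
    percent injected dose per gram, integrates organ time-activity curves
    by the trapezoidal rule with a physical-decay tail, extrapolates
    mouse uptake to a human phantom by relative-organ-mass scaling, and
    applies the MIRD schema with ICRP-26 and ICRP-60 tissue weighting
    against regulatory dose limits. Includes a synthetic biodistribution
    generator with blocked and non-blocked cohorts so the whole pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
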