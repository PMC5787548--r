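Package: normorph
Title: Normative Brain Morphometry Statistics for Individual Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a normative database of region-wise brain morphometric
    parameters (volumes, cortical thickness, surface area, curvature,
    gray-white contrast) from healthy-control tables such as FreeSurfer
    stats exports, and scores individual patient visits and follow-up
    series against it. Age trends are modelled by polynomials whose degree
    is selected with Bonferroni-corrected nested F-tests after two-pass
    interquartile-range outlier rejection. Measurement error is estimated
    from short-interval repeat scans, artifact probabilities and validity
    odds from observed outlier rates, and per-region p-values are inflated
    by the measurement error before false-discovery-rate controlled
    highlighting. Longitudinal atrophy progression is quantified by linear
    residue trends tested against cross-sectional aging, and the whole
    pipeline can be calibrated by leave-one-out cross-validation in the
    control cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
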