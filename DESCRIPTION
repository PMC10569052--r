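Package: aqfuse
Title: Quality Assurance and Model Fusion for Low-Cost PM2.5 Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a raw network of low-cost optical PM2.5
    sensors into corrected observations and fusing them with a gridded
    air-quality model field. Implements a five-step network quality
    assurance scheme (relocation and coverage filters, blind network
    correlation screening, gain and weekly-offset correction, and
    singular-spectrum-analysis drift assessment), robust colocation
    calibration by iteratively reweighted least squares, optimal
    interpolation of seasonal point observations into a background
    concentration field, and leave-one-out cross-validation of the
    resulting analysis. A synthetic-data generator emulating a winter
    wood-smoke deployment makes every stage testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
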