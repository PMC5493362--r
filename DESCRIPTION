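Package: fuzzyair
Title: Mamdani Fuzzy Inference for Air Pollution and Respiratory
    Hospital Admissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A Mamdani fuzzy inference engine (trapezoidal membership
    functions, minimum rule activation, maximum aggregation, area-centre
    defuzzification) together with a ready-made epidemiological model that
    maps daily concentrations of particulate matter (PM10), ozone (O3) and
    sulfur dioxide (SO2) plus apparent temperature to a predicted daily
    count of hospital admissions for asthma and pneumonia.  Includes
    lag-aware validation (Pearson correlation and ROC area under the curve
    with Hanley-McNeil confidence intervals), a synthetic daily-series
    generator with a planted lagged exposure-response association, CSV and
    YAML/JSON configuration input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
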