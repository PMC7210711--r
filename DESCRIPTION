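Package: heattol
Title: Thermal Death Time Curve Analysis of Heat Knock-Down in Zooplankton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing static heat-tolerance assays of small aquatic
    ectotherms such as Daphnia magna. Detects time to immobilisation (knock-down
    time) from swimming-velocity time series exported by video tracking
    software, fits thermal death time curves (semi-logarithmic regressions of
    knock-down time on exposure temperature) to derive the temperature
    sensitivity coefficient z and the extrapolated upper thermal limit CTmax,
    and compares candidate linear mixed models (crossed random intercepts for
    culture beaker and measuring run, maximum likelihood) with AICc and Akaike
    weights. Includes a seeded synthetic-assay generator that reproduces the
    statistical structure of a multi-run, multi-temperature knock-down
    experiment so that the full pipeline can be exercised and calibrated by
    simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
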