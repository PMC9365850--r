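Package: islerad
Title: Island Invasive Vertebrate Eradication Records and Timeline Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesising island invasive-vertebrate eradication
    records in the DIISE export dialect: parsing and validating event tables,
    applying the standard inclusion filters, computing group success-rate
    summaries and annual/cumulative activity series, and a timeline analysis
    that fits cubic regression splines with GCV-selected equidistant knots
    under a lognormal scatter model, derives pointwise bootstrap confidence
    bands for the trend curve and its first two derivatives, and extracts
    multi-year periods of significant growth, acceleration, or deceleration.
    Includes a synthetic event-table generator with known ground truth so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
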