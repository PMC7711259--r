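Package: surgecap
Title: Elective Surgery Utilization, Revenue and Hospital Surge Capacity
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how cancelling or resuming elective surgery
    changes hospital and intensive-care bed capacity and gross hospital
    revenue.  Includes a synthetic administrative-claims generator with
    ground-truth labels, revenue-code based classification of admissions
    into elective surgical, non-elective surgical and non-surgical
    categories with 30-day complication attribution, person-day utilization
    and bed-allocation accounting, gross-revenue aggregation by major
    diagnostic category, and a state-level epidemic surge-demand model that
    convolves incidence curves with length of stay to obtain peak census
    and patient-to-bed overcapacity ratios under elective-cancellation
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
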