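Package: claimstroke
Title: Identify Acute Ischemic Stroke Admissions in Health Insurance Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based identification of acute ischemic stroke (AIS)
    admission episodes in longitudinal health-insurance claims data.
    Reconstructs admission episodes from claim lines, evaluates 17
    temporally windowed claims-code key identifiers (diagnosis, imaging,
    reperfusion, intervention, antithrombotic new-user exposure and
    rehabilitation), classifies each episode through a diagnosis-code
    stratified decision tree, and validates calls against a linked
    gold-standard registry with sensitivity, specificity, accuracy, PPV
    and NPV on a random development/validation split. Ships a synthetic
    claims-plus-registry cohort generator with exact flag-to-claims
    round-trip guarantees so the whole pipeline is testable without
    access to national claims data.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
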