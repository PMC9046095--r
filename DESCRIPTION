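Package: eproutes
Title: Emergency-Presentation Routes to Cancer Diagnosis from Linked Registry and Admissions Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cancer diagnoses as emergency presentations (EP) by
    linking tumour registrations to hospital inpatient admissions under broad
    and narrow operational definitions with a configurable pre-diagnosis
    window; summarises EP frequency by jurisdiction, cancer site, age group,
    sex, stage and year with Wilson score intervals; estimates EP-risk and
    EP-mortality odds ratios by logistic regression; pools jurisdiction
    estimates by random-effects meta-analysis with a definition-type
    moderator; and fits the jurisdiction-level ecological association between
    EP percentage and 1-year net survival. Includes a synthetic linked
    registry generator emulating the two-table structure of non-shareable
    jurisdictional data, and a federated aggregate-only exchange format with
    small-cell suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    metafor,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
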