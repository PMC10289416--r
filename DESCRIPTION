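Package: flexscreen
Title: Flexible Stage Distribution Model for Cancer Screening Cost-Effectiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form cohort model for assessing the cost-effectiveness of
    extending an ongoing breast cancer screening programme to new age groups.
    Screening policies act on per-age-group incidence rates and conditional
    stage distributions; expected life-years, expected treatment and screening
    costs, expected breast cancer deaths and incremental cost-effectiveness
    ratios (ICER) are computed in closed form for a cohort followed from the
    first invitation age to a fixed horizon. Includes scenario builders for
    younger/older screening extensions and one-way sensitivity analyses, an
    individual-level Monte Carlo simulator used as an independent validation
    oracle, a synthetic parameter generator emulating the structure of Finnish
    registry inputs, and CSV/JSON parameter-file readers and writers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
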