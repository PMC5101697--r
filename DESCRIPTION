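Package: qicompare
Title: Comparability of Care-Process Quality Indicators Between Survey and
    EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores process quality indicators for physical therapy care from
    item-level patient-case records under two measurement frameworks: the
    proportional framework used for provider surveys (actual score divided by
    maximum possible score per case) and the dichotomous framework used for
    data extracted from electronic health records (a case scores 1 only when
    every step of the clinical reasoning process was followed). Harmonizes
    survey responses into the dichotomous framework, aggregates to therapist
    level, and compares matched therapists across the two data sources on
    completeness (proportion of cases without missing item values) and
    correctness (agreement of mean indicator scores), using matched-pairs
    Wilcoxon signed-rank tests, relative change with a relevance threshold,
    and a validity filter for indicators with too few valid extracted scores.
    Includes a seeded synthetic cohort generator emulating the hierarchical
    practice/therapist/case structure, ceiling effects, per-item missingness
    and supplier-level extraction deviations, so the whole pipeline is
    testable without access to clinical data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
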