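Package: balsteward
Title: BAL-Informed Antibiotic Stewardship Analysis for Critically Ill
    Pneumonia Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies day-by-day antibiotic prescription breadth around an
    episode-defining bronchoalveolar lavage (BAL) with the Narrow Antibiotic
    Therapy (NAT) score, classifies episode resistance from multiplex-PCR
    resistance genes and quantitative-culture phenotypes, taxonomizes
    PCR/culture concordance, detects antibiotic de-escalation and cessation,
    and compares composite clinical outcomes across pneumonia etiologies with
    sample odds ratios, Fisher's exact test and Mann-Whitney U tests. Includes
    a seeded synthetic ICU cohort generator so every pipeline stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
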