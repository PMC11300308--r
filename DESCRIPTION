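Package: cachexstage
Title: Cancer Cachexia Staging and Survival Analysis from Clinical and
    Patient-Reported Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based staging of cancer-associated cachexia in pancreatic
    ductal adenocarcinoma from routinely collected laboratory values and
    patient-reported instruments (abridged PG-SGA, ESAS-r, Canadian Problem
    Checklist, EORTC QLQ-C30/PAN26). Classifies patients into four ordered
    stages (non-cachexia, pre-cachexia, cachexia, refractory cachexia) and a
    dichotomous weight-loss based status, derives prognostic laboratory scores
    (Glasgow Prognostic Score, neutrophil-to-lymphocyte ratio), summarizes
    symptom burden and supportive-care needs, and analyzes stage-linked overall
    survival with Kaplan-Meier, log-rank, Cochran-Armitage trend, and Cox
    proportional-hazards methods. Includes a seeded synthetic-cohort generator
    that emulates the stage-conditional criterion structure and stage-dependent
    survival of a real diagnosis-time cohort so every pipeline step is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
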