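Package: pwudflag
Title: Rule-Based Identification of Hospitalized People Who Use Drugs from
    Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for flagging hospital encounters of people who use drugs
    (PWUD) from free-text clinical notes and ICD-10 codes. Implements a
    lexicon/regular-expression matcher with negation, history and
    false-trigger assertion handling, per-encounter note-fraction thresholds
    (10/25/50 percent), ICD-10 visit and patient-history code flags, a
    registry of boolean encounter classifiers, and the accompanying
    evaluation statistics: sensitivity, specificity, per-class F1, event and
    nonevent net reclassification indices with prevalence weighting, the
    McNemar paired test, and McNemar power and sample-size calculations.
    A synthetic-corpus generator with known ground truth supports end-to-end
    validation without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
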