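Package: lrasim
Title: Microsimulation of FIT-Based Colorectal Cancer Screening and
    Post-Polypectomy Surveillance Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A person-level microsimulation of fecal immunochemical test (FIT)
    based colorectal cancer screening in a population aged 50-74, built to
    compare follow-up strategies after removal of 1-2 low-risk adenomas:
    surveillance colonoscopy at 5 years versus return to routine FIT screening
    at 5 years. Simulates adenoma onset, growth, regression and progression to
    colorectal cancer across three size classes, threshold-dependent FIT
    positivity keyed to a person's most advanced lesion, colonoscopy pathways
    with polypectomy and complication sampling, undiscounted health-system
    cost accounting in three groups, and paired replicate experiments with
    t-based Monte Carlo confidence intervals for incremental outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
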