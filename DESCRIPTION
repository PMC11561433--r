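Package: telefocus
Title: Detection and Analysis of Lifestyle-Focused Telecare Conversations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing annotated nurse-telecare call corpora in
    chronic disease management. Computes per-call topic utterance ratios,
    detects per-patient lifestyle-focused calls from ratio trajectories using
    a median (L1) regression trend with jump and sustain rules, compares call
    content and structure between call groups with cluster-robust linear
    regression and Holm-Bonferroni correction, tabulates expert concern
    evaluations, and associates focus-call counts with inpatient utilization
    (admission counts, average length of stay) via Spearman rank tests and
    Cohen's d. Includes a synthetic cohort generator with planted ground truth
    for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, yaml, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, quantreg, sandwich, lmtest, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
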