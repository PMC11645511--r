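Package: panelqc
Title: Data-Quality Assessment for Web Survey Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and comparing the quality of respondent data
    collected on web survey panels (convenience panels such as crowdworker
    pools versus probability-based panels). Implements respondent screening
    (speeding, incompleteness, fake-condition endorsement), careless-response
    metrics (quadratically weighted kappa on repeated item pairs,
    straight-lining rules, the mean-root-of-pairs statistic, Winsorized
    response burden), Cronbach alpha with a cross-sample reliability test,
    algorithmic detection of copied open-text responses, raking (iterative
    proportional fitting) with weight trimming and total-absolute-imbalance
    diagnostics, benchmark comparison of point estimates on a T-score metric,
    and correlation-matrix comparison across samples. A synthetic-cohort
    generator with known ground truth (honest, straight-lining, speeding,
    misrepresenting and copy-paste personas plus demographic selection bias)
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
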