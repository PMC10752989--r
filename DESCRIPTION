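Package: volrely
Title: Reliability Evaluation of Volumetric Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for evaluating and comparing volumetric
    biomarker measurement methods (e.g. automated hippocampal volumetry).
    Implements accuracy metrics (volume percentage error, Pearson
    correlation with interpretation bands), test-retest metrics (volume
    percentage difference, consistency intraclass correlation with
    F-based confidence intervals), a gated hypothesis-testing battery
    (Kolmogorov-Smirnov normality gate, paired t / exact Wilcoxon
    signed-rank, variance F-test, Fisher z-test on correlations,
    confidence-interval overlap decisions), and a Bayesian hierarchical
    linear mixed-effects model fitted by Markov chain Monte Carlo whose
    between- to within-subject variance ratio summarizes longitudinal
    reliability. A synthetic-data generator reproduces the statistical
    structure of accuracy, test-retest, and longitudinal volumetry
    studies so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr, rjags
Config/testthat/edition: 3
RoxygenNote: 7.3.3
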