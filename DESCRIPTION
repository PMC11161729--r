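Package: ptxrank
Title: Platinum-Response Biomarker Discovery from Spectral-Count Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and prioritizing protein biomarkers of
    response to platinum-based adjuvant chemotherapy from label-free
    spectral-count proteomics of paired patient cohorts. Implements
    sample-sum normalization of spectral counts, a beta-binomial
    likelihood-ratio test for differential protein expression between
    poor- and good-response groups, nested significance tiers, cross-cohort
    candidate intersection with hypergeometric overlap testing, exhaustive
    and randomized combinatorial signature search with leave-one-out
    cross-validated logistic classifiers, a cumulative robustness and
    signature scoring rubric for candidate ranking, recurrence-free
    survival analysis (Kaplan-Meier, log-rank, abundance-quartile splits),
    unsupervised cohort structure analysis, and a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
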