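Package: wmlpatterns
Title: Spatial White Matter Lesion Patterns and Progression to Cognitive
    Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up discovery of spatial white-matter-lesion (WML)
    patterns that predict progression to mild cognitive impairment (MCI)
    or dementia in an elderly cohort. Computes total and relative regional
    (frontal, parietal, temporal, occipital) WML volumes, searches for
    prognostic patterns with an exhaustive Gini-impurity decision tree
    stabilised by a 10-fold cross-validation consensus rule, and relates
    the resulting patterns to MCI/dementia risk with delayed-entry Cox
    proportional-hazards models on the age timescale, with
    interval-censored onsets dated by the visit-midpoint rule. Includes a
    synthetic longitudinal cohort generator emulating the statistical
    structure of a community-dwelling elderly MRI sub-study (scheduled
    visits, death and loss-to-follow-up censoring, pattern-dependent
    hazards) so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
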