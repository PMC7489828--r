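Package: tractrisk
Title: Census-Tract Excess Cardiovascular Death Risk from Semisynthetic Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds semisynthetic individual-level populations from census-tract
    demographic marginals, insurer claim counts and survey donor records, assigns
    each person a cardiovascular disease (CVD) death risk from a configurable
    proportional-hazards risk equation, and contrasts the tract-level expected
    risk with observed, directly age-standardized death rates to obtain an
    excess-risk (expected minus observed) surface per 100 000 persons. Provides
    global Moran's I permutation tests for spatial clustering of the excess-risk
    surface, Bonferroni-corrected univariate and backward-stepwise multivariate
    regressions of excess risk on social and biological determinants, rank
    composites of determinants, and counterfactual determinant-improvement
    scenarios. A synthetic-data generator with planted, serialized ground truth
    emulates every input (tract lattices, demographics, survey pools, claims,
    determinants, death counts) so the whole pipeline is testable end to end.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
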