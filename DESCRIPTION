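Package: twopath
Title: Two-Stage Profile Clustering and Stability Selection for
    Longitudinal Self-Harm Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-stage analysis of adolescent self-harm in
    longitudinal cohort data: unsupervised discovery of behavioural
    subgroups among young people who self-harm (a self-organizing map on
    z-scored Strengths and Difficulties Questionnaire subdomain and Mood
    and Feelings Questionnaire scores, followed by k-means on the learned
    node weights, validated with the silhouette coefficient), and
    per-sweep risk-factor discovery via bootstrapped L1-regularised
    logistic regression with cross-validated penalty selection, a 95
    percent inclusion-frequency stability rule, and holdout validation by
    ordinary logistic regression.  Includes k-nearest-neighbour
    imputation with a 30 percent missingness exclusion rule,
    Greenhouse-Geisser corrected mixed ANOVA for developmental
    trajectories, a synthetic cohort generator with planted subgroups and
    planted risk-factor effects for end-to-end testing, and a
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
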