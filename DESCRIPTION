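Package: aaiscreen
Title: Valence-Arousal Suitability Screening of Dogs for Animal-Assisted
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores dog behavioural aptitude tests for animal-assisted
    interventions (AAI) on a valence-arousal circumplex grid, classifies
    dogs as suitable, pending suitability, or unsuitable via a triangular
    suitability region, scores caregiver questionnaires, quantifies
    caregiver-versus-test agreement (Cohen's kappa, concordance) and
    two-rater reliability (intraclass correlation), and runs the
    accompanying nonparametric comparison battery (Kruskal-Wallis with
    eta-squared, Dunn-Holm post hoc, Mann-Whitney with rank-biserial
    effect size, paired Wilcoxon, Shapiro-Wilk) including paired salivary
    cortisol analysis. Ships a seeded synthetic-cohort generator that
    emulates the data structure of a 38-dyad screening study so the whole
    pipeline is testable end to end without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
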