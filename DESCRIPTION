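Package: tg18cds
Title: Guideline-Encoded Decision Support for Acute Cholecystitis (TG18)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable clinical decision-support engine for
    acute cholecystitis built on the Tokyo Guidelines 2018 (TG18). Encodes the
    TG18 diagnostic criteria, severity grades, surgical-risk rules and
    management pathways as a declarative, versioned rule file compiled into a
    queryable knowledge graph; extracts clinical features from structured case
    vignettes with a lexicon and pattern layer; grades severity and recommends
    management with a full rule-activation trace; arbitrates answers from
    multiple pluggable agents by confidence-weighted voting with hard
    constraint checking; and provides the statistical harness (exact binomial
    intervals, ROC/AUC with DeLong comparison, Fleiss' and Cohen's kappa,
    McNemar, ANOVA with Tukey and Bonferroni, Fisher/chi-square switching)
    used to evaluate rater cohorts on multiple-choice question banks. A
    synthetic vignette generator with planted ground truth makes every
    component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
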