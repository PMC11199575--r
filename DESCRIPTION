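Package: ivret
Title: Responder Analysis of Pre/Post Exercise Intervention Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying inter-individual variability in response to
    exercise training (IVRET) in pre/post intervention designs. Classifies
    participants as responders or non-responders per outcome using
    typical-error cutoffs on change scores, quantifies within- and
    between-category adaptation with mixed between-within ANOVA, Bonferroni
    post-hoc contrasts, baseline-adjusted ANCOVA and standardized effect
    sizes, measures cross-outcome concordance of response categories
    (chi-squared independence, odds ratio, Cramer's V, flow tables),
    probes baseline moderation with two-line regression comparison, and
    estimates repeated-measures correlations with subject-specific
    intercepts and a common slope. A synthetic cohort generator with known
    ground truth (true individual responses, technical error, cross-outcome
    response correlations) makes the whole pipeline testable without real
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    MASS,
    car,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
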