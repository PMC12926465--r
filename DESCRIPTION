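Package: framesim
Title: Theory-Based Household Agents and Realism Evaluation for a
    Simulated Infant Formula Shortage
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale digital-twin simulation of household
    formula-seeking behavior during a two-week infant formula shortage in
    a stylized five-zone urban environment, contrasting
    Belief-Desire-Intention household agents grounded in the Health
    Belief Model, the Theory of Planned Behavior and Social Cognitive
    Theory against rule-based control agents, together with the full
    FRAME realism-evaluation pipeline: condition-blind vignette
    rendering, counterbalanced presentation orders, a synthetic Likert
    rater generator, and the within-subjects statistical suite (paired t
    with Cohen's dz, intraclass correlation, repeated-measures ANOVA
    with Mauchly's test and the Greenhouse-Geisser correction,
    Holm-adjusted post-hoc comparisons, bootstrap confidence intervals
    and a-priori power analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
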