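Package: respdiv
Title: Response Diversity and Adaptive-Capacity Gaps in Multi-Environment
    Variety Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess within-species response diversity of crop
    cultivars to agroclimatic variation, designed around northern-European
    perennial forage variety trials.  Daily weather series are segmented
    into fall-hardening, winter and growth periods; fourteen agroclimatic
    variables are computed per trial environment; environments are
    stratified into low/moderate/high tertiles; and a cultivar-by-category
    linear mixed model (REML, Type-III F tests, least-squares means)
    quantifies genotype, environment and genotype-by-environment effects.
    Variables with a significant environment effect but no significant
    interaction are flagged as gaps in adaptive capacity.  A seeded
    synthetic-data module generates weather and trial yields with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
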