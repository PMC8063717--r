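Package: prospectmeta
Title: Simulation and Analysis of Prospective Metacognitive Judgments in a
    Two-Stage Perceptual Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulator of a two-stage random-dot-kinematogram
    probability-matching task, in which an observer first chooses between an
    "internal" option (reward hinges on their own perceptual accuracy at a
    given motion coherence) and an "external" option (reward delivered with a
    stated probability), and then performs the chosen perceptual decision.
    Implements the accompanying behavioral statistics: type I and type II
    ROC areas, meta-d'/d' (M-ratio), prospect-theory probability-weighting
    fits, lagged logistic choice and performance models, challenge versus
    inevitable trial contrasts, and the beta-timecourse slope statistic for
    region-of-interest signals, together with parameter-recovery harnesses
    on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
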