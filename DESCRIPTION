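Package: ttbsearch
Title: Take-the-Best Heuristic Models of Search in Explorable Pay-Off Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation and estimation toolkit for human search in
    gradually explorable pay-off landscapes. Generates peaked 2-D (63 x 63) and
    1-D pay-off landscapes by a sub-landscape/Gaussian-filter/merge procedure,
    simulates a lexicographic take-the-best cue cascade (exploration-radius,
    not-visited, pay-off and novelty cues) with epsilon-noise and a stochastic
    stopping/ignoring/returning rule for the transition from exploration to
    exploitation, plus alternative exploration (probabilistic, hill-climbing,
    blind, random) and exploitation (normative, early-stop, simple-returning)
    models. Provides trajectory metrics (pay-off curves, visit-density maps,
    revisit fractions, cue-usage frequencies, safety levels), model-comparison
    distances with k-fold cross-validation, and parameter-recovery fitters for
    the noise level, the stop/ignore slopes, the truncated-normal safety level
    and the logistic cue-choice rule.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
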