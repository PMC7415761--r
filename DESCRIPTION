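Package: canishow
Title: Detection and Mixed-Model Analysis of Showing Behavior in Dog-Owner Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing referential "showing" communication between
    dogs and their owners in hidden-object tasks. Reads and validates
    behavioral-coding event logs on a 0.20 s time grid, detects showing
    events as temporal pairings (overlap, or alternation within a 2 s
    window) of a box-directed component with an owner-directed
    attention-getting component, classifies the 15 showing types, and
    derives per-observation accuracy, choice-rate and effort scores.
    Provides the matching inferential layer: one-sample and paired t tests
    with Cohen's d and noncentral-t confidence intervals, binomial-logit
    mixed models for communication success, Gaussian mixed models for
    showing effort with Satterthwaite degrees of freedom, AIC-based model
    selection with likelihood-ratio tests, inter-coder reliability with
    Cicchetti bands, and a seeded synthetic dyadic event-log generator so
    the whole pipeline is testable without video-coded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
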