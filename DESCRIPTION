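Package: ridephysio
Title: Physiological Analysis of Passenger Reactions During Autonomous Rides
Version: 0.1.0
Authors@R: person("ridephysio", "maintainers", email = "maintainers@ridephysio.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing passenger psychophysiology
    during (self-)driven rides with unexpected road events. Computes EEG
    affectivity (frontal alpha asymmetry) and arousal band-power indices,
    multifractal spectrum widths of eye- and head-displacement series via the
    Chhabra-Jensen direct method, blink frequencies per route segment, and
    Condition x Route-event repeated-measures ANOVA with generalized
    eta-squared and Tukey post hocs. Ships a synthetic-cohort generator with
    planted effects (band-structured EEG, multiplicative-cascade displacement,
    scheduled blinks) so every stage is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
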