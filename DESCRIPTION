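Package: navbci
Title: Bayesian Target Inference for Robot Navigation from Noisy
    Brain-Signal Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and classification toolkit for semi-autonomous
    robot navigation guided by reactive electroencephalography (EEG).
    A virtual robot navigates a grid towards an unknown target while a
    noisy multi-class classifier of the user's event-related potentials
    labels each action (towards target, target reached, further away,
    stepped off; correct/false target identification).  The package
    implements Bayesian posterior inference over candidate target
    locations using confusion-matrix observation models, reactive and
    random baseline strategies, a stepwise linear discriminant analysis
    (SWLDA) layer for event-related potential epochs with a synthetic
    ERP generator, and the speed-accuracy metrics (percentage of targets
    correctly identified, mean normalised steps) used to compare
    strategies across evidence-stringency settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
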