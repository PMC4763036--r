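Package: pointorigin
Title: Analysis of Virtual Point-to-Origin Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing virtual point-to-origin (homing) experiments
    in which observers watch a passively simulated two-segment excursion
    (straight, turn, straight) through a star field and indicate the egocentric
    quadrant containing the origin. The package simulates outbound-path
    kinematics and derives the quadrant predicted by each hypothesised response
    strategy (turner, non-turner, non-mover, spinner), classifies participants
    from their quadrant answers by a consistency criterion, fits multinomial
    and binary logistic models of classification on demographic factors with
    likelihood-ratio term tests, extracts pairwise odds ratios with Wald
    intervals under every baseline rotation, builds bootstrap null
    distributions of classifier accuracy, and generates synthetic cohorts with
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
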