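Package: tdregimes
Title: Strategic Test-Day Recording Regimes for Lactation Yield and
    Genetic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation of milk-recording strategies for
    tropical dairy herds. Simulates pedigree-structured lactations from
    the Wood incomplete-gamma curve with correlated genetic and
    environmental variation in the curve parameters, estimates lactation
    yield from sparse test-day records by the test-interval method and by
    Wood-model fitting, searches for strategically timed test-day
    sampling regimes by iterative pool elimination, compares regimes by
    mean square error of prediction and breeding-value ranking agreement
    (animal-model BLUP), and translates estimation accuracy into
    progeny-testing capacity via selection-index formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
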