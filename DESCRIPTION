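Package: anfisdry
Title: Convective Drying Kinetics and Neuro-Fuzzy Modelling of Blanched Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for thin-layer convective drying experiments on
    warm-water-blanched fruit: moisture-ratio kinetics, slope-method effective
    moisture diffusivity under the Fick sphere solution, Arrhenius activation
    energy, and drying energy accounting; a from-scratch first-order
    Takagi-Sugeno adaptive neuro-fuzzy inference system (ANFIS) with hybrid
    least-squares/gradient training and checking-set epoch selection; a
    membership-function structure search; ANFIS-based sensitivity ranking of
    drying factors; and a synthetic drying-data generator for end-to-end
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
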