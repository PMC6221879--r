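Package: igevar
Title: Indirect Genetic Effects on Social Interaction Coefficients and
    Inherited Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic model in which pairwise social
    interactions generate heritable differences in trait variability.
    Growth rate of each individual in a pair responds to the weight
    difference with its group mate through an interaction coefficient b
    that is itself a heritable trait with direct (resistance to
    competition) and indirect (cooperativeness) genetic components.
    Provides a seeded Monte-Carlo breeding-program simulator with
    Mendelian inheritance, closed-form oracles for the within-pair weight
    difference, summary statistics linking competition to variability
    (within-group and phenotypic variance, group-mate correlation,
    sire-family variability correlations), multi-generation selection
    experiments (mass selection, group selection on the mean or the
    variance), and an ordinary-least-squares estimator of the
    population-average interaction coefficient from time-series pair
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
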