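Package: spikesensor
Title: Spiking-Sensor Model of Slowly Adapting Type I Tactile Afferents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a spiking-sensor model of slowly adapting
    type I (SAI) tactile afferents. Synthetic ramp-and-hold force traces,
    standing in for a force sensor embedded in a skin-like elastic
    substrate, are low-pass filtered, linearly transduced into
    transmembrane current from force and its rate of change, and
    integrated by a leaky integrate-and-fire membrane (fourth-order
    Runge-Kutta, absolute refractory period) to produce spike trains.
    Interspike-interval statistics over the dynamic ramp-up and static
    hold phases are compared against observed afferent responses through
    a fractional-sum-of-squares objective, the six free model parameters
    are fit by first-order response-surface steepest ascent, and fitted
    models are validated on held-out traces with randomized-complete-block
    ANOVA and Tukey pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
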