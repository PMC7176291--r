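Package: amrcycle
Title: Stochastic Eco-Evolutionary Dynamics of Microbial Populations
    Under Periodic Antimicrobial Exposure
Version: 0.1.0
Authors@R:
    person("amrcycle", "maintainers", email = "maintainers@amrcycle.org",
           role = c("aut", "cre"))
Description: Exact event-driven (Gillespie) simulation of a
    sensitive/resistant/compensated microbial population with logistic
    growth under periodic alternations of antimicrobial absence and
    presence, together with the analytic theory for the probability that
    the population is eradicated before compensated resistance fixes:
    Moran-model fixation probabilities and lineage sojourn times,
    birth-death mean first-passage (extinction) times, time-inhomogeneous
    branching-process survival of resistant lineages atop a
    deterministically decaying sensitive background, and the assembled
    extinction probabilities for biostatic and biocidal drugs above and
    below the minimum inhibitory concentration.  Includes parameter-sweep
    drivers reproducing extinction-probability curves, phase-diagram
    heatmaps and predicted transition lines, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
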