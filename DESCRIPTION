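Package: v1scale
Title: Scaling and Synaptic Compensation in a Spiking Model of Macaque V1 Layer 4Ca
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire network model of the
    input layer (4C-alpha) of macaque primary visual cortex, with tools to
    construct seeded network realizations at reduced cell density (1/n
    cortices), drive them with drifting-grating LGN input, ambient Poisson
    pulses and Layer-6 feedback, and study how downscaling degrades firing
    rates, orientation selectivity, gamma rhythms and simple/complex cell
    structure. Implements a current-difference-based synaptic-weight
    compensation algorithm that steers reduced cortices back to full-size
    firing rates, together with the analysis metrics (orientation tuning
    surfaces, circular variance, modulation ratio, population spectra,
    source-resolved current decomposition) needed to evaluate them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
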