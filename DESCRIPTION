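Package: ecodune
Title: Coupled Vegetation and Aeolian Sediment Transport Cellular Automaton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A lattice simulator of semi-arid dryland landscapes that couples
    a vegetation dynamics model (grass, shrub and tree life cycles driven by
    seasonal precipitation, neighbourhood facilitation/competition and
    compound environmental stress) to a Werner-style sand-slab transport
    model (wind-event sampling from seasonal Weibull distributions,
    vegetation wake corridors, shadow zones and angle-of-repose
    avalanching). Includes fire and grazing disturbance regimes, a synthetic
    seasonal climate-forcing generator, landscape statistics (population
    density, grass:shrub ratio, tree cover, total sediment transport) and
    drivers for equilibrium, transient and fire-by-grazing factorial
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
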