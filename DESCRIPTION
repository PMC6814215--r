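Package: fuzzyrisk
Title: Fuzzy Logic Decision Support for Climate-Driven Biomass Loss Risk
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processes gridded dynamic global vegetation model ensembles
    with an EEMS-style fuzzy logic decision support model to map the risk of
    climate-driven biomass loss. Provides linear fuzzy normalization between
    false/true thresholds, And/Or/Union operators with per-cell source
    attribution, a declarative logic-tree evaluation engine, modal
    vegetation-type departure scoring, ensemble reducers (minimum, mean,
    maximum) and a standard-deviation based uncertainty layer, area-weighted
    regional summaries, fire-versus-mortality driver attribution, and a
    synthetic data generator emulating multi-climate-future ensembles so the
    entire pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
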