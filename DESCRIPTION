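Package: pollcoex
Title: Stochastic-Topological Coextinction Cascades in Plant-Pollinator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pollinator extinction cascades in quantitative
    bipartite plant-pollinator networks with a hybrid coextinction model:
    plants survive the loss of pollinator j with probability 1 - IPD*d_ij
    (stochastic), while pollinators go extinct only when their last plant
    partner is lost (topological). Provides estimation of intrinsic plant
    dependence on pollinators (IPD) from pollinator-exclusion experiments,
    three removal scenarios (random, generalist-first, specialist-first),
    four model variants, a pure topological baseline, per-plant survival
    curves and robustness, keystone-pollinator identification, exact
    small-network enumeration oracles, and a synthetic community generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
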