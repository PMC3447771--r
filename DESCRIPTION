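Package: antscape
Title: Spatially Explicit Ant-Scale-Ladybeetle Dynamics in a Coffee Agroecosystem
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic cellular automaton for arboreal ant nests coupled to
    lattice population dynamics of a scale-insect pest and a predatory
    ladybird beetle on a toroidal 120 x 90 grid. Provides the five-step
    synchronous update rule (Holling type II predation, linear ant-nest
    mortality and expansion, propagule rain, density-dependent local and
    global migration, Rosenzweig-MacArthur scale growth, habitat-dependent
    beetle survival), scenario experiments probing how beetle-driven
    clustering of ant nests feeds back on beetle persistence, spatial
    point-pattern statistics (single-linkage cluster sizes with power-law
    fits, Ripley's K/L with Monte Carlo envelopes), and genetic-algorithm
    parameter calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
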