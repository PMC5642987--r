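Package: champr
Title: Pruning Modularity Partition Ensembles to Domains of Optimality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing for ensembles of hard network partitions
    produced by modularity-maximization heuristics. Each partition is
    reduced to scalar coefficients that make its (multilayer) modularity an
    affine function of the resolution parameter gamma and the interlayer
    coupling omega. The ensemble is then pruned to the admissible subset of
    partitions that are optimal somewhere in parameter space, with each
    survivor's domain of optimality mapped as an interval in gamma
    (single-layer) or a convex polygon in (gamma, omega) (multilayer).
    Includes adjusted-mutual-information tools for comparing partitions
    across adjacent domains, a pluggable heuristic sweep driver with a
    built-in Louvain-style greedy optimizer, planted-partition generators
    for single-layer and temporally coupled multilayer benchmarks, and
    readers/writers for edge-list, GML, ensemble and coefficient-table
    formats together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
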