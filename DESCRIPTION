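Package: chiralwalk
Title: Continuous-Time Chiral Quantum Walks on Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of continuous-time quantum walks whose
    Hamiltonians carry complex hopping phases (Peierls phases) that break
    time-reversal symmetry. Provides a phased-graph representation with a
    gauge-transformation calculus (tree-phase removal, loop-flux invariants),
    unitary and Markovian (Lindblad) propagation with absorbing sinks and
    dephasing, transport figures of merit (half-arrival time, transport
    speed, first occupancy maximum, asymptotic sink efficiency), multi-start
    bounded optimization of edge phases, and ready-made model systems: a
    directional quantum switch, chains of triangular switches, even and odd
    cycles, a seven-site Fenna-Matthews-Olson exciton model, and small-world
    and scale-free network ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
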