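# chiralwalk

Continuous-time **chiral quantum walks**: quantum transport on graphs
whose Hamiltonians carry complex hopping phases that break time-reversal
symmetry.

## The problem

A standard continuous-time quantum walk evolves a single excitation under
the real weighted adjacency matrix of a graph, `H[n,m] = J_nm`.  Reality
of the couplings makes the dynamics time-reversal symmetric (TRS): the
site-to-site transfer probability obeys
`P_S→E(t) = P_S→E(−t) = P_E→S(t)`, so transport can never be biased in
one direction.  Attaching a phase to an edge,

    ⟨n|H|m⟩ = J_nm · exp(i θ_nm),   θ_mn = −θ_nm,

keeps `H` Hermitian but breaks TRS.  The phases themselves are partly
gauge: a diagonal unitary `diag(exp(i α_n))` shifts
`θ_nm → θ_nm + α_n − α_m` without touching any transfer probability, so
the physical control parameters are the *loop fluxes* — oriented phase
sums around cycles.  Trees have no cycles, hence no chiral transport;
rings with half-quantum flux (`π`) show perfect destructive interference.
`chiralwalk` implements this calculus, unitary and Markovian (Lindblad)
propagation with absorbing sinks and dephasing, the transport figures of
merit (half-arrival time `τ½`, speed `ν½ = 1/τ½`, first occupancy
maximum, asymptotic sink efficiency), multi-start bounded phase
optimization, and the model systems where these effects matter: a
directional quantum switch, chains of triangular switches, even/odd
cycles, a seven-site FMO exciton model, and Watts-Strogatz /
Barabási-Albert network ensembles.

It is written for quantum-transport and quantum-biology researchers who
want reproducible, scriptable simulations of phase-controlled transport.

## Worked example

```r
library(chiralwalk)

# the quantum switch: one control phase steers transport from S to E or F
m0 <- first_maximum(make_switch(0),       horizon = 30)   # achiral
m1 <- first_maximum(make_switch(-pi/2),   horizon = 30)   # toward E
m2 <- first_maximum(make_switch(+pi/2),   horizon = 30)   # away from E

# with absorbing sinks at both poles
eff <- transport_efficiency(make_switch(-pi/2, sinks = TRUE), "S", "sink_E")

# the trapped eight-triangle chain
ach <- transport_summary(make_triangle_chain(trap = TRUE),                horizon = 300)
chi <- transport_summary(make_triangle_chain(theta = -pi/2, trap = TRUE), horizon = 300)
enhancement(ach, chi)
```

which prints

    P_S->E first maximum:  achiral 0.3663 | theta=-pi/2  0.8584 | theta=+pi/2  0.0292
    enhancement: +134.3%   suppression: -92.0%
    preferred-pole sink efficiency: 83.0%
    chain tau_half: 38.2 -> 5.29  (speed enhancement 623%)

Reading: at the transport-favouring phase `θ = −π/2` the first maximum of
the S→E occupancy grows by 134% over the achiral switch, while the
opposite sign suppresses it by 92% (the two poles trade places exactly
under `θ → −θ`); with unit-rate sinks at both poles, 83% of the walker is
absorbed at the preferred pole.  On the chain of eight triangular
switches with a unit-rate trap, the common control phase cuts the
half-arrival time from 38.2 to 5.29 time units — a ~620% transport-speed
enhancement from phases alone, with all coupling magnitudes untouched.

A command-line front end wrapping the same functions (subcommands
`simulate`, `optimize`, `ensemble`, `gauge`, `zoo`) ships in
`inst/cli/cqw.R`; the methods vignette
(`vignettes/chiral-quantum-walks.Rmd`) documents the model, the
calibrated default geometries, and every numerical choice.

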