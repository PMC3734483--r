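---
title: "Chiral quantum walks: models, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral quantum walks: models, metrics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralwalk)
```

## The model

A continuous-time quantum walk on an undirected graph evolves a single
excitation under the Hamiltonian built from the weighted adjacency matrix,
$H_{nm} = J_{nm}$ with real $J_{nm} \ge 0$, plus on-site energies
$\epsilon_n$ on the diagonal.  Because every matrix element is real, the
dynamics is invariant under the time-reversal operation $T$ (complex
conjugation in the site basis), which forces
$P_{S\to E}(t) = P_{S\to E}(-t) = P_{E\to S}(t)$ for the site-to-site
transfer probability (STP) $P_{S\to E}(t) = \langle E|\rho(t)|E\rangle$,
$\rho(0)=|S\rangle\langle S|$.  No achiral walk can be biased in one
direction.

`chiralwalk` studies what happens when hopping terms acquire complex
phases,
$$ \langle n|H|m\rangle = J_{nm}\, e^{i\theta_{nm}}, \qquad
   \theta_{mn} = -\theta_{nm}, $$
which keeps $H$ Hermitian but generally breaks time-reversal symmetry:
transport can now be steered, sped up, or suppressed entirely.  The
`phased_graph` object stores exactly this parameter set
$(J_{nm}, \theta_{nm}, \epsilon_n)$; phases live on a canonical edge
orientation (lower site index $\to$ higher site index) and are reduced to
$(-\pi,\pi]$ on every mutation so that serialized graphs and test
expectations are unique.

Open-system dynamics follows the Lindblad master equation
$$ \dot\rho = -i[H,\rho]
   + \sum_k c_k \left( L_k \rho L_k^\dagger
   - \tfrac12\{L_k^\dagger L_k,\rho\} \right), \qquad
   L_k = |m_k\rangle\langle n_k|,\; c_k \ge 0, $$
with three channel kinds: absorbing *sinks* (traps), realized as auxiliary
basis states fed by one-way jumps so that total occupancy stays 1 and
"transport efficiency" is literally the sink population; site-to-site
relaxation channels; and pure dephasing $L=|n\rangle\langle n|$.  We use
$\hbar = 1$ and measure couplings in a reference unit, so time is
dimensionless (for the FMO model the config file fixes the unit to
picoseconds via an explicit cm$^{-1}$ conversion constant).

## Gauge freedom

A diagonal unitary $U = \mathrm{diag}(e^{i\alpha_n})$ changes edge phases
as $\theta_{nm} \mapsto \theta_{nm} + \alpha_n - \alpha_m$ while leaving
every STP invariant (localized initial states and occupancy measurements
are eigenstates of $U$; jump operators pick up phases that cancel in the
dissipator).  Two consequences shape the package:

* **Trees are achiral in disguise.**  Sweeping outward from a root, every
  phase on an acyclic graph can be cancelled (`remove_tree_phases()`), so
  chirality cannot affect transport on chains or trees.
* **Loop fluxes are the real parameters.**  The oriented phase sum around
  any cycle (`loop_phase_sum()`) is gauge invariant;
  `normalize_spanning_tree()` produces a canonical form with all phases
  concentrated on co-tree edges.  The spanning tree is grown
  breadth-first from the lowest-indexed site with neighbours visited in
  index order, a deterministic tie-break that makes canonical forms
  reproducible.

Because only fluxes matter, "which edge carries the control phase" in the
model systems below is a labelling convention; the packaged choices fix
the sign so that $\theta = -\pi/2$ is always the transport-enhancing
value.

## Propagation

All propagators are spectral and therefore give *analytic* time
dependence — any $t$ can be evaluated exactly, which the metric
root-finders exploit:

* **Unitary:** eigendecomposition of the Hermitian $H$;
  $P_{S\to m}(t) = |\langle m|e^{-iHt}|S\rangle|^2$.  Negative times are
  supported (they propagate with $-H$).
* **Pure sink loss:** when every incoherent term is a one-way jump into a
  sink and the walker starts localized, the site sector evolves under the
  effective non-Hermitian Hamiltonian
  $H_{\rm eff} = H - \tfrac{i}{2}\sum_k c_k |n_k\rangle\langle n_k|$, and
  each sink occupancy is the closed-form integral of its inflow
  $c_k |\psi_{n_k}(t)|^2$.  This route handles the 32-node network
  ensembles in milliseconds per evaluation.
* **General Lindblad:** the dense Liouvillian superoperator is
  diagonalized; if its eigenbasis is numerically ill-conditioned the
  package falls back to scaling-and-squaring matrix exponentials (a
  Padé-13 implementation for complex matrices).  Backward Lindblad
  evolution is refused with an explicit error — the master equation is
  not reversible.

The test suite cross-checks both open-system routes against direct ODE
integration of the master equation with `deSolve::zvode` at $10^{-7}$.

## Transport metrics

* `half_arrival_time()` — earliest $t$ with target occupancy $\ge 1/2$
  (closed threshold; the bisection tolerance of $10^{-6}$ time units makes
  the open/closed distinction immaterial).  Sink occupancies are monotone,
  so sinks use pure bisection; site occupancies oscillate and are scanned
  on a grid (default step 0.05) before root polishing.  A walker that
  never crosses within the horizon returns `NA` flagged `reached = FALSE`.
* `first_maximum()` — first interior local maximum of the target series,
  polished with `optimize()`; on stored trajectories a spline interpolant
  at 10x the stored density avoids grid aliasing.  Monotone series return
  the endpoint flagged as a boundary.
* `transport_efficiency()` — asymptotic sink occupancy; closed form for
  pure-loss systems, horizon-based with an explicit inflow convergence
  check ($<10^{-8}$ per unit time) otherwise.
* `enhancement()` — percentage comparisons between two summaries
  ($\nu_{1/2}$ ratio, first-max ratio, $\tau_{1/2}$ reduction).

The default metric horizon is 100 time units, which resolves all
unit-coupling model systems; the network ensembles use 2000 because
achiral realizations with nearly dark target sites fill their sink very
slowly, and truncating them would bias ensemble means.

## Model systems and calibrated geometry

**Switch.**  A triangle with three wires to poles S, E, F and one control
phase across the junction.  Junction devices of this kind are usually
drawn, not tabulated, so the package fixes a documented reference
configuration: unit couplings, a one-site input wire and two-site output
wires
(`make_switch(theta, pole_wire = 2, source_wire = 1)`).  With this
geometry the first maximum of $P_{S\to E}$ at $\theta=-\pi/2$ is
2.34 times the achiral value (+134%), at $\theta=+\pi/2$ it is reduced by
92%, and with unit-rate sinks at both poles the preferred-pole absorption
is 83% — the biasing itself is insensitive to wire lengths, but the
percentage values are geometry-dependent, which is why the defaults are
part of the documented contract.  Note the quoted suppression is the
percentage *reduction* of the first maximum: since $\theta \to -\theta$
exactly exchanges the poles, a strong enhancement of E necessarily comes
with a strong (here 92%) suppression of F, never a mild one.

**Triangle chain.**  Eight corner-sharing triangles
(`make_triangle_chain()`), injected through a one-site wire and trapped
directly at the far corner.  The input wire matters: starting the walker
on the bare end corner leaves exactly half the initial state in dark
eigenstates that never reach the trap, so the achiral sink saturates at
1/2 and a half-arrival time does not exist.  With the wire, the unit trap
rate reproduces an achiral $\tau_{1/2}$ of 38.2 and a chiral
($\theta=-\pi/2$) value of 5.29 — a ~620% speed enhancement.  The trap
rate is exposed (`trap_rate`) and the acceptance suite re-derives it by
one-parameter calibration; it lands at 1.000 to three digits, so the unit
rate is the package default rather than a tuned constant.

**Cycles.**  `make_cycle(n, pi_edge = TRUE)` demonstrates the even/odd
dichotomy: a single $\pi$ flux on an even ring makes the antipodal site
exactly dark at all times (the two interfering arms cancel identically,
with or without a trap), while odd rings can only redistribute transport.

**Networks.**  `make_watts_strogatz()` implements the canonical
small-world rewiring: every node keeps the near end of its own $k/2$ ring
edges and only far endpoints are rewired with probability $p$, so degrees
never fall below $k/2$ and the graph stays sink-optimizable at the target
(a degree-1 target would have a single, gauge-trivial incident edge).
Disconnected draws are regenerated with an incremented sub-seed.  Source
and target are the maximally distant pair, ties broken by lowest index.
`make_barabasi_albert()` provides the scale-free counterpart.

**FMO.**  `load_fmo()` assembles the standard seven-site exciton model
from an editable YAML config.  The packaged file carries the Adolphs &
Renger (2006) site energies and couplings together with the standard
open-system rates (dephasing 2.1 ps$^{-1}$, trapping 1 ps$^{-1}$ from
site 3 into the reaction-centre sink, recombination 1 ns$^{-1}$); negative
couplings become $\pi$ phases, holding $|J|$ fixed while phases vary.  The
`A1`/`A2` edge subsets default to the seven and three strongest couplings.
Because these parameters are assembled from the literature rather than a
single canonical table, quantitative phase-optimization gains depend on
the config; the package asserts the structural facts — optimized speed is
never below baseline, and the seven-edge search at least matches the
three-edge one (the test warm-starts the larger search from the nested
optimum so the inclusion is honoured numerically).

## Phase optimization

`optimize_phases()` runs bounded L-BFGS-B on $[-\pi,\pi]^k$ with
finite-difference gradients from multi-start: `n_restarts` seeded uniform
points plus, always, the system's current phases — which makes the
"never worse than baseline" guarantee structural.  Two numerical choices
matter: the finite-difference step ($10^{-5}$) must sit far above the
internal $\tau_{1/2}$ bisection tolerance ($10^{-10}$), otherwise the
gradient is noise and the optimizer cannot leave its start point; and
phases are re-wrapped to $(-\pi,\pi]$ only on reporting, since the
objective is $2\pi$-periodic and the box boundary is not a true
constraint.  `ensemble_optimize()` applies this machinery across seeded
Watts-Strogatz realizations (achiral sink $\tau_{1/2}$, then optimization
of the target-incident phases) and reports per-$p$ and pooled mean
percentage reductions with full seed provenance.

## What the generators do and do not emulate

The synthetic systems reproduce the *structural* conditions of the
transport problem — topology, unit couplings, trap placement, seeded
randomness — but idealize everything else: baths are flat Markovian rates
(no structured spectral densities, no temperature dependence), only one
excitation is ever present, and static disorder is absent.  Passing tests
therefore certify the chiral-transport mechanism and the numerics, not
quantitative predictions for any particular physical device; for the FMO
system in particular the numbers inherit the uncertainty of the
literature parameter set in the config file.

## Problem sizes and runtime choices

The test-suite defaults keep everything on one CPU in minutes: property
checks use random graphs of up to 8 sites (where dense Liouvillians are
81-dimensional), the network ensemble runs 50 realizations per
$p \in \{0.05, 0.2, 0.5\}$ with 3 optimizer restarts (the enhancement
statistics stabilize well before 200 realizations), and FMO optimizations
use 2 restarts.  All are plain function arguments; scaling them up
changes runtime, not code.

## Known limitations

Single-exciton subspace only; Markovian (Lindblad) baths only; local
optimization with multi-start rather than global guarantees; no gradient
back-propagation through the propagators; dense linear algebra throughout
(graphs beyond a few hundred sites would need sparse/Krylov methods).
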