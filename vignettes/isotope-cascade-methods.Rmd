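---
title: "Methods: SCC-decomposed isotope labeling dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SCC-decomposed isotope labeling dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocascade)
```

## The model

isocascade simulates the transient propagation of a ¹³C label through a
metabolic network that is at *metabolic* steady state (fluxes `v` and
pool sizes `C` constant) but *isotopically* instationary after a step
change in substrate labeling at `t = 0`.  The state variables are mass
isotopomer fractions: for an elementary metabolite unit (EMU) of `n`
carbons, the fractions `m_0 … m_n` of molecules carrying that many
heavy atoms.  Each mass isotopomer obeys a balance

$$C_i \frac{dm}{dt} \;=\; \sum_p v_p\,(\text{reactant MIDs composed to this
weight}) \;-\; v_{\text{out}}\, m,$$

where production runs over the EMU reactions generating the fragment
(a condensation composes weights additively, which is the MID
convolution) and `v_out` is the total consumption of the metabolite.
Assumptions inherited from the EMU framework: atom transitions are
known and deterministic, reactant labeling states are independent at
the point of condensation (well-mixed pools), substrate labeling is
constant in time, and isotope effects on rates are negligible.
Reversible steps are encoded as two irreversible reactions; symmetric
molecules carry several atom-map alternatives per reaction, each
weighted `1/n` of its flux.  Growth dilution is not modeled.

## Reorganization into strongly connected components

Rather than treating an EMU's whole MID vector as the modeling unit,
every (EMU, weight) pair is a node of a directed graph; edges run from
reactant mass isotopomers to each product mass isotopomer they can
compose.  Two structural facts drive the design:

* weight never decreases along an edge, so every cycle — and hence
  every strongly connected component — lives within one weight class;
* only ancestors of the measured mass isotopomers influence the
  measurement, so the graph is pruned to the backward closure of the
  measured nodes first.

Pruning is a reverse breadth-first search from the measured nodes on
the transposed graph; it retains exactly the same node set as a full
transitive-closure (Floyd–Warshall) computation, which the test suite
keeps as an independent reference, at far lower cost.  SCC detection
uses igraph's strong-components routine, cross-checked in the suite
against a mutual-reachability oracle.  The components are then sorted
by weight and, within a weight, by a topological order of the
condensation DAG.  Kahn's algorithm breaks ties by the
lexicographically smallest member node, which makes the (weight, index)
labels reproducible across runs; the notion of "adjacent" components
for aggregation is defined as *consecutive in this within-weight
order*, a choice the order makes unambiguous.

The aggregation parameter λ (default 10, the packaged toy and
generated fixtures use the same default) greedily merges consecutive
same-weight components until each merged unit holds at least λ mass
isotopomers; the last unit of a weight class may be smaller.  Merging
consecutive blocks of a valid topological linearization preserves its
validity, and the SCC count is weakly decreasing in λ.  Substrate
(input) mass isotopomers are *constants* of the system, not SCCs: they
enter the equations through the input term, and they are excluded from
component counts — with this convention the toy network yields 14
components.  When both the raw and the aggregated granularity are of
interest, `scc_partition(graph, 1)` and `scc_partition(graph, lambda)`
report both counts.

## Two assembly backends

Both backends are assembled from the same term set and differ only in
how multi-reactant production is evaluated:

* **tensor** — the 0/1 transition tensor of each EMU reaction is stored
  in coordinate form (one entry per weight composition) and contracted
  against the parent states entry by entry;
* **vector** (default) — unimolecular production, consumption and
  substrate input fold into one sparse matrix per block; each
  multi-reactant reaction gathers its reactants' full MID vectors,
  convolves them, and scatters the result onto the product weights
  present in the target block.  Missing (pruned) weights gather as
  zero; this cannot corrupt a present product weight, because every
  reactant weight that can reach a present product node is itself an
  ancestor and therefore present.

The two routes agree to below 1e-12 at random states, which the test
suite asserts on the toy and on generated fixtures.  The pool-size
matrix is diagonal and is inverted once at assembly; all coefficients
carry `1/C`.

`convolve_mid()` realizes the fragment-joining product: the MID of a
fragment formed from two independent fragments is the convolution of
their MIDs, restricted to the index set of the target block.  That
restriction is what makes the operation specific to each (reactant,
reactant, target) triple.

## Sensitivities

Fluxes are parameterized through an orthonormal basis `N` of the null
space of the stoichiometric matrix restricted to balanced metabolites
(`v = v₀ + N u`), computed by a QR factorization with a fixed pivot
order so free-flux indices are reproducible.  Pool parameters are the
pool sizes of metabolites that survive pruning.  Because the right-hand
side is linear in `v` and every row carries exactly one `1/C_i`
factor, the forcing terms are cheap: flux directions reuse the
assembled term set with `N`-weighted coefficients, and
`∂f/∂C_m = -f · 1[met = m] / C_m`.  The sensitivity blocks satisfy
`dS/dt = J S + ∂f/∂θ` along the same cascade, start at zero, and are
integrated together with the base state (sharing its step size in
adaptive mode, justified by the similar steepness of a metabolite's
labeling curves and their parameter derivatives).  Correctness is
checked three ways: a closed-form single-pool solution, central finite
differences on the toy (agreement to 1e-4 with relative step 1e-5),
and the implicit-function-theorem limit at stationarity.

## Integration

**Constant step.**  Classical explicit RK4 — stage weights
`(1, 2, 2, 1)/6`, stages at `t, t+h/2, t+h/2, t+h`.  All SCC blocks
evaluate each stage against their parents' values advanced by the same
stage increment, so the cascade integrator is exactly RK4 on the
monolithic system.  (A printed variant of this update with weights
`(1, 2, 3, 1)` and an `h/2` final stage circulates in the literature;
it is not a consistent 4th-order tableau and is treated here as a
typographical artifact.)  `integrate_constant()` warns when the chosen
step exceeds the explicit stability bound of the fastest block, where
round-off amplification would silently degrade conservation.

**Adaptive step.**  The embedded Cash–Karp 4(5) pair with
per-component tolerance `tol_scaling·|y| + tol_addition` (defaults
1e-9 and 1e-7, mapping the two tolerance factors onto the standard
relative + absolute form).  The step is selected on a *pilot*
subsystem: the shortest prefix of the topological order whose blocks
cover at least one EMU of every metabolite, restricted to weight-0
nodes (a metabolite with no weight-0 node contributes its lightest
node).  A topological prefix is ancestor-closed, so the pilot is a
well-defined closed subsystem, and weight-0 dynamics never depend on
heavier nodes.  Acceptance is decided on the pilot *before* the step is
broadcast, so downstream blocks never roll back.  Accepted steps grow
by the `err^(-1/5)` rule (safety 0.9, growth capped at 5×), rejected
steps shrink by `err^(-1/4)` (floored at 0.1×).

One guard is essential: the pilot watches only m₀ values, so it cannot
observe numerical instability of heavier isotopomers of a *fast* pool
once its m₀ has relaxed.  The broadcast step is therefore capped at
`2.5 / ρ`, where `ρ` is a Gershgorin bound on the fastest relaxation
rate over all block-internal matrices — just inside the real-axis
stability region of the explicit pair.  On non-stiff problems (the toy:
`ρ = 2 s⁻¹`) the cap is inactive; on fixtures whose pool sizes span
three decades it is what keeps the broadcast-step scheme stable, at the
cost of more steps.  Residual tolerance-scale error on heavier
isotopomers of fast pools remains an inherent property of the pilot
design and is visible in conservation reports of stiff fixtures.

**Output.**  States are recorded at every accepted step; arbitrary
times are served by cubic Hermite interpolation on the stored states
and slopes (local error `O(h⁴)`, exact at the knots).

## The parallel contract

Parallelism is specified as a scheduling contract, not a thread
primitive: one task per (SCC block, RK stage, step), where a block may
start stage `s` only after the blocks it reads from (condensation
parents plus convolution sources) have delivered stage `s−1`.  The
implementation is a deterministic scheduler simulation — round-robin
worker queues, one ready task per worker per round, a watchdog that
aborts if a full round makes no progress — whose per-block arithmetic
is shared with the serial steppers (identical accumulation order), so
trajectories are bit-for-bit identical for any worker count, and the
pilot step-size sequence is computed once per step and broadcast.
These two facts are asserted in the tests; wall-clock speed-up is a
hardware property and is deliberately out of scope.

## Diagnostics and reference solvers

* `spectral_check()` reports the eigenvalues of every block's internal
  matrix (within-block production plus the consumption diagonal, over
  `C`).  For flux-balanced models all real parts are strictly negative;
  imaginary parts are reported rather than assumed zero.  The stiffness
  ratio is max/min of the real-part magnitudes, flagged undefined when
  the minimum is numerically zero (e.g. a zero-flux pool).
* `stationary_solution()` solves the algebraic EMU balance size class
  by size class (linear solves; multi-reactant terms only involve
  strictly smaller, already-solved EMUs) and serves as the `t → ∞`
  oracle.
* `isotopomer_oracle()` is a deliberately independent route: it builds
  the complete positional-isotopomer ODE system (2ⁿ states per
  metabolite, guarded at 10⁴ total) straight from the reaction atom
  maps and integrates it with `deSolve::lsoda` at tolerance 1e-11,
  marginalizing to MIDs.  The SCC-based simulation matches it to below
  1e-8 on the toy and on small generated networks.

## Synthetic fixtures

`toy_model()` is the printed 8-reaction network.  Its flux vector is a
constructed balanced solution scaled to a substrate uptake of 10
(v₁ = 10, v₂ = 6, v₃ = 2.5, v₄ = v₅ = v₈ = 1.75, v₆ = 1.5, v₇ = 2.5);
pool sizes are order-unity (B 5, C 4, D 5, E 3, F 6, concentration
units matching the fluxes' time base) so the labeling transient
resolves within the default 10 s horizon; the substrate is fully
¹³C-labeled and whole-molecule F is measured.

`random_network()` emulates the toy's topology at scale: a labeled
2-carbon substrate feeds a randomly wired core of 2-carbon metabolites
(random atom permutations, cycles allowed), pairs of which condense
into 4-carbon products that are cleaved back (creating genuine
multi-node SCCs) or drained; every deficit is closed exactly by a sink
or uptake, so generated models are flux-balanced and strictly positive
by construction.  Pool sizes are log-uniform over 1e-6 to 1e-3
(micromolar to millimolar) and fluxes are scaled to 1e-4 concentration
units per second, giving turnover times from ~10 ms to ~10 s — wide
enough to exercise the stiffness machinery.  What the generator does
*not* emulate: cofactor coupling, carbon counts beyond 2/4,
compartmentation, measurement noise, and natural-abundance correction;
passing tests on these fixtures demonstrate correctness of the
machinery, not biological realism of any particular network.
`sample_flux_distribution()` draws balanced positive flux vectors by
rejection in the null-space polytope around the stored fluxes.

## Problem sizes and numerical choices in the test suite

The suite runs the toy at its default settings (10 s, step 0.005,
2000 steps) for the oracle, conservation, parallel-determinism and
adaptive-agreement checks; the dense adaptive reference uses step
5e-4.  Finite-difference sensitivity checks use a 2 s horizon.
Generated-network oracle checks integrate 300 steps at
`h = 0.03 / k_max` so RK4 truncation stays below the 1e-8 comparison
band.  Oracle-equivalence fixtures stay at or below 10 metabolites to
respect the positional-isotopomer guard.

## Known limitations

* Explicit integrators only; severely stiff networks pay for stability
  with step count rather than switching to an implicit scheme.
* The inverse problem (fitting fluxes and pools to measured labeling
  data) is out of scope; the package provides the forward model and
  its sensitivities that such a fitter needs.
* Isotope granularity is mass isotopomers of EMUs; cumomer or bondomer
  instantiations of the same SCC machinery are not built.
* No natural-abundance correction or measurement-error model.
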