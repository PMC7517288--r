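---
title: "Public goods dynamics on rank-3 hypergraphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Public goods dynamics on rank-3 hypergraphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hyperpgg` studies how *group* (higher-order) interactions change the
evolution of cooperation in structured populations. This vignette documents
the model, the parameters that matter, the numerical and design choices made
where the design was genuinely open, and what the package's synthetic
structures do and do not emulate.

## The model

**Structure.** A population of `N` players occupies the vertices of a *simple
hypergraph*: hyperedges of cardinality 2 ("links") represent pairwise
interactions, hyperedges of cardinality 3 ("triangles") represent irreducible
three-player interactions, and no hyperedge is contained in another. The
*2-section* — the graph linking any two vertices that share a hyperedge — is
the social substrate on which imitation happens.

Structures are built by *promotion*: starting from a clustered base network,
a fraction `p` of its 3-cliques is selected uniformly at random, each becomes
a triangle, and every link contained in a selected triangle is removed. The
base network is exactly the 2-section of the result for every `p`, so varying
`p` changes only the *order* of the interactions, never who interacts with
whom. That isolation of the higher-order effect is the point of the design.

**Game.** Each round, every player plays a public goods game in each incident
hyperedge: cooperators contribute `b` to each group pot, the pot is scaled by
the synergy factor `alpha` and split equally among the `m` members. A
player's round payoff in one group is

$$f(\sigma) = b\left[\left(\frac{\alpha}{m} - 1\right)\sigma +
\frac{\alpha(m-1)}{m}\,q\right],$$

with `sigma` its strategy (1 = cooperate) and `q` the fraction of cooperating
co-members; `total_payoff()` sums this over incident hyperedges. Payoffs are
per-round quantities: they are recomputed from scratch each round, never
accumulated, which makes them linear in `alpha` (the fact the trap analysis
exploits). The social dilemma exists for `alpha < m`.

**Update.** Strategy revision is synchronous Fermi imitation: every player
draws *one* neighbour uniformly at random in the 2-section and adopts its
strategy with probability `1/(1 + exp(-beta (f_j - f_i)))`. Drawing a
same-strategy neighbour is an explicit no-op that consumes no further random
variate, which keeps the random-number stream (and hence reproducibility
bookkeeping) independent of the payoff state. The homogeneous states `c = 0`
and `c = 1` are absorbing; a run ends at absorption or at the cutoff `tmax`,
in which case the last density is taken as the asymptotic value.

**Reciprocity measure.** For a structure with hyperedge-cardinality fractions
`p_m`, an infinite well-mixed population transitions abruptly at
`alpha_cr = sum_m m p_m`. The survival onset `alpha_surv` is the smallest
synergy at which the Monte Carlo mean asymptotic density rises above zero,
and `r = alpha_surv / alpha_cr` quantifies structural reciprocity; `r < 1`
means the structure sustains cooperation below the well-mixed threshold.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `alpha` | synergy factor (pot multiplier, dimensionless) | — | swept; dilemma for `alpha < m` |
| `b` | per-group contribution (payoff unit) | 1 | only the product `beta * b` matters dynamically |
| `beta` | selection strength of the Fermi rule | 1 | strong-but-noisy selection; `0.1` is the weak-selection regime |
| `c0` | initial cooperator fraction | 0.5 | unbiased start; `round(c0 N)` cooperators drawn uniformly |
| `p` | fraction of 3-cliques promoted | — | interpolates pairwise (`p = 0`) to 3-uniform (`p = 1`) |
| `tmax` | round cutoff | 2e4 | long enough that non-convergence signals topological trapping, not slow mixing |
| `epsilon` | "density above zero" onset threshold | `1/(2N)` | half a player; the smallest meaningful density excess |

Base-network generators: Holme–Kim (`N = 500`, `m = 3`, triad probability
`p_t = 1`, mean degree ≈ 6), Dorogovtsev–Mendes (`N = 500`, mean degree → 4)
and Erdős–Rényi `G(N, M)` with `M = round(N k / 2)` (mean degree pinned
exactly, default 6). HK with `p_t = 1` and DM both have complete triangle
percolation (every link in a 3-clique), so promotion can reach a 3-uniform
structure at `p = 1`; DM additionally satisfies the exact per-vertex identity
`k3(p=1) = k2(p=0) - 1`, which the tests assert.

## Monte Carlo protocol

For each parameter set, `mc_experiment()` generates several replicate
structures, runs a batch of independent realizations per structure and per
grid point (fresh random initial state each), averages density and
convergence time *within* each structure and then *across* structures, and
counts non-converged runs per 100. The grid is expressed in
`r = alpha / alpha_cr(H)` with each structure playing at its own critical
synergy, so curves from different structures align. The full-scale reference
protocol is 10 structures × 100 runs; the package's tests and the acceptance
script run a reduced scale chosen once — `N = 500`, 3 structures × 25 runs
per point, `r` step 0.01, cutoff 5e3 (2e4 where the measured quantity is a
time or a non-convergence count) — which resolves the onset to the grid step
while keeping a full verification run in minutes on one CPU.

Seeding: a master seed spawns per-structure and per-run sub-seeds up front,
so results are reproducible and independent of evaluation order. When only
the onset is needed, the ascending grid scan stops once the mean density
exceeds `epsilon` (`stop_when_above`), which is exact for the onset statistic
and saves the super-critical part of the sweep.

## Analytic layer

* **Mean field** (`mean_field_step()`, `alpha_cr_mean_field()`): identical
  mean m-degrees and uncorrelated local states give a one-dimensional map for
  the density with interior flow changing sign at `alpha_cr = <m>`; the
  degree route and the hyperedge-count route must agree on every structure
  (two-route consistency, tested to machine precision).
* **Finite size** (`alpha_cr_finite()`): on a complete m-uniform hypergraph
  of `N` vertices under strong selection, the transition sits at
  `m (N-1)/(N-m) > m`. The simulator reproduces this on `N = 20` (and the
  approach to `m` on large dense random 3-uniform structures).
* **Cooperator hubs** (`hub_threshold()`, `r_hub()`, `hub_invasion()`): a
  cooperator hub survives any single defector challenge above a threshold
  synergy obtained by equating its payoff to its neighbours' average; for
  s-uniform structures this reduces to
  `r_hub = 1/(1 + (s-1)(q0_hub - qbar0_d xi_s))` with `xi_s` the
  neighbourhood-to-hub degree ratio. Scale-free structures have small `xi_s`,
  hence `r_hub` well below 1, and `r_hub` decreases with the interaction
  order `s` — the analytic footprint of reciprocity growing with the order of
  interactions.
* **Isolated defectors** (`defector_payoff_gap()`,
  `survive_and_invade_prob()`, `competition_conditions()`): the payoff gap to
  an isolated defector's average cooperator neighbour is linear in `alpha`;
  when the defector's degrees sufficiently exceed its neighbours', the gap
  *shrinks* with `alpha`, sustaining defector hold-outs that widen the
  transition region — and the triangle-rich conditions are weaker than the
  pairwise ones precisely when the shared-triangle ratio `kappa_d/kappa_c`
  exceeds 3/4.
* **Traps** (`bottleneck_threshold()`, `find_bottleneck_candidates()`,
  `trap_census()`): bottleneck traps are bridge-vertex configurations whose
  payoff lines cross at threshold synergies; between two thresholds the
  favoured imitation direction alternates and the configuration cycles.
  Structures with complete triangle percolation admit none. The census
  contrasts non-convergence on the original structures with two null models.

## Numerical and design choices

These were the genuinely open points; each was decided once and is listed
here rather than hidden in code.

* **Vertex ids.** In-memory objects are 1-based (R and igraph convention);
  the plain-text interchange format is 0-based, converted on read/write.
* **Promotion count.** `round(p * n_cliques)` (round-half-to-even) cliques
  are selected, from the full clique list, before any edge removal.
* **Onset estimator.** `alpha_surv` is read off the *across-structure
  averaged* density curve (matching how the reference curves are drawn), not
  estimated per structure and averaged; `epsilon = 1/(2N)` by default, both
  configurable.
* **Connected ER realizations.** The dynamics experiments resample
  `G(N, M)` until connected: an isolated vertex is a frozen strategist, so a
  disconnected realization can never absorb and every run would report
  `tmax` for structural-triviality reasons, masking the actual convergence
  behaviour. `generate_er()` keeps plain `G(N, M)` by default.
* **Hub definition.** Hubs are selected on the generalized degree `k(i)`
  (configurable to 2-section degree); `xi_s` uses per-hub neighbourhood
  means averaged across hubs. The s-independent treatment
  `xi = (xi_2 + xi_3)/2` is available for curve reproduction.
* **Clustering-preserving rewiring.** A proposed link exchange is accepted
  only if the triangle count of *every* vertex it can affect (the four
  endpoints and the common neighbours of the removed and added pairs) is
  unchanged — degrees being fixed, this preserves the entire per-vertex
  clustering vector exactly, which is the guarantee the null model is used
  for. Checking only the two drawn vertices would leave second-order leaks.
* **Rewiring step counting.** `n_steps` counts *accepted* exchanges, with a
  proposal cap (`max_attempts`, default 200 per requested step) so graphs
  with few admissible moves terminate; the realized counts are returned as
  attributes. The clustering-preserving null accepts only a small fraction
  of proposals, so at a fixed attempt budget it stays close to the original
  graph — consistent with its role of *preserving* the trap-carrying
  structure.
* **3K-preserving rewiring acceptance.** The two drawn vertices must have
  equal degree, and then the two far endpoints of the drawn links must have
  equal degree (the literal reading of the procedure); this preserves
  `P(k, k')` and `P(k, k', k'')` exactly, which the tests assert by
  histogram comparison.
* **Mean-field iteration.** Fixed points to `|Δc| < 1e-12` or 1e6
  iterations; fixed points classified by the sign of the payoff gap.
* **Trap detection at desk scale.** A run is "trapped" iff it reaches `tmax`
  unconverged; `find_bottleneck_candidates()` flags bridge links (links
  outside every 3-clique) as the locations where bottleneck traps can live.

## What the synthetic structures do and do not emulate

The HK and DM generators reproduce the features the analysis needs:
heavy-tailed degrees, high transitivity, complete triangle percolation, and
near-neutral assortativity. They do not emulate spatial embedding, community
structure, assortative mixing, weighted or temporal interactions, or group
sizes above three. Passing tests therefore demonstrate the mechanism —
higher-order reciprocity driven by degree heterogeneity and clustering — on
this family of structures; they do not certify magnitudes for real social
networks, and the analytic layer itself predicts a weaker effect on
assortative structures.

## Known limitations

* Dynamics are restricted to rank ≤ 3 hypergraphs (the containers are
  general; the promotion algorithm and the invasion formulas are rank-3).
* Synchronous updates only; no asynchronous or accumulated-payoff variants,
  no mutation, and the synergy factor is group-size independent.
* The trap census characterizes traps statistically through null models; it
  does not enumerate trap topologies.
* The isolated-defector layer treats all neighbours as the average vertex;
  its channel-preference comparisons are therefore qualitative.
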