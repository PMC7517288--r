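# hyperpgg

Simulation and analysis toolkit for the evolution of cooperation under
**higher-order interactions**. Pairwise network models cannot distinguish
three people interacting as three pairs from three people interacting *as a
group*; `hyperpgg` represents populations as rank-3 **simple hypergraphs**
(links plus irreducible three-player "triangles") and asks how moving
interactions from pairs to groups changes the survival of cooperation.

It is written for researchers in evolutionary game theory and network
science who want a reproducible, tested reference implementation of:

* **structure generation** — clustered base networks (Holme–Kim with triad
  formation, Dorogovtsev–Mendes, Erdős–Rényi) and the *promotion* algorithm
  that converts a fraction `p` of 3-cliques into triangular hyperedges while
  leaving the pairwise projection (2-section) untouched, so `p` isolates the
  pure effect of interaction order;
* **dynamics** — a synchronous public goods game: in every group of size
  `m`, cooperators pay `b`, the pot is scaled by the synergy `α` and split
  equally, giving the round payoff
  `f(σ) = b[(α/m − 1)σ + (α(m−1)/m) q]`; strategies update by Fermi
  imitation of one uniformly drawn 2-section neighbour,
  `P(adopt) = 1/(1 + e^{−β Δf})`, all players simultaneously (compiled core,
  ~10⁴ rounds on a 500-vertex hypergraph in tens of milliseconds);
* **structural reciprocity** — the measured onset `α_surv` of cooperation
  relative to the well-mixed threshold `α_cr = Σ_m m p_m`:
  `r(p) = α_surv/α_cr < 1` means the structure sustains cooperation below
  the mean-field transition, and decreasing `r(p)` in `p` means group
  interactions reinforce it;
* **analytics** — the mean-field map and its critical synergy, the
  finite-size threshold `α_cr^m = m(N−1)/(N−m)`, cooperator-hub invasion
  thresholds (`r_hub = 1/(1 + (s−1)(q₀^hub − q̄₀^d ξ_s))`), isolated-defector
  survival/invasion probabilities and the degree/clustering competition
  conditions, bottleneck-trap thresholds from payoff lines;
* **null models** — degree-preserving rewirings that additionally preserve
  either every vertex's local clustering or the joint 3K-distribution
  `P(k, k′, k″)`, used to show that topological traps ride on local
  clustering.

## Worked example

```r
library(hyperpgg)
set.seed(42)

# a 3-uniform hypergraph from a Dorogovtsev-Mendes network
g <- generate_dm(300)
H <- promote_cliques(g, p = 1)
H
#> <hypergraph> 300 vertices, 298 hyperedges (298 of size 3)
alpha_cr(H)
#> [1] 3

# one trajectory above the survival onset
res <- run_pgg(H, game_params(alpha = 2.2, beta = 1), c0 = 0.5)
res
#> <pgg_run> n = 300, c_final = 1.000, absorbed after 50 rounds

# the reciprocity endpoint r(1): ascending sweep in r = alpha/alpha_cr
reciprocity_endpoint("dm", p = 1, beta = 1, n = 300, runs = 20,
                     n_hypergraphs = 2, tmax = 5e3, seed = 1)
#> # A tibble: 1 x 7
#>   model     p  beta r_surv alpha_surv alpha_cr n_runs_per_point
#>   <chr> <dbl> <dbl>  <dbl>      <dbl>    <dbl>            <dbl>
#> 1 dm        1     1   0.55       1.65        3               40
```

Cooperation survives from `r ≈ 0.55`, i.e. at barely more than half the
well-mixed critical synergy — strong structural reciprocity. The analytic
hub layer explains the magnitude: hubs at the 99th degree percentile of a
scale-free 3-uniform structure have neighbourhoods far sparser than
themselves (`ξ_s ≪ 1`), which pins their invasion threshold near the same
value:

```r
hub_invasion(promote_cliques(generate_hk(500, 3, 1), 1), 99, c0 = 0.5)
#> # A tibble: 1 x 6
#>   percentile     s n_hubs ks_hub  xi_s r_hub
#>        <dbl> <int>  <int>  <dbl> <dbl> <dbl>
#> 1         99     3      5   97.2 0.152 0.542
```

`autoplot()` methods draw density/convergence-time curves for sweeps and
trajectories for single runs; `tidy()`/`glance()` return tibbles. A thin
command-line wrapper (`inst/cli/hyperpgg.R`) exposes `generate`, `sweep`,
`analyze` and `rewire` subcommands over the package's plain-text hypergraph
format (one hyperedge per line, 0-based ids).

## Package layout

| | |
|---|---|
| `R/hypergraph.R`, `R/io.R` | simple-hypergraph container, validation, 2-section, m-degrees, plain-text I/O |
| `R/generators.R` | HK / DM / ER base networks, 3-clique enumeration, promotion |
| `R/payoffs.R`, `R/dynamics.R`, `src/` | game payoffs, Fermi rule, compiled synchronous dynamics |
| `R/sweep.R`, `R/experiment.R` | Monte Carlo sweeps, onset estimation, reciprocity endpoints, config-driven experiments |
| `R/mean_field.R`, `R/invasion.R` | mean-field map, finite-size threshold, hub and isolated-defector analysis |
| `R/rewire.R`, `R/traps.R` | null-model rewirings, corrected convergence time, bottleneck thresholds, trap census |
| `vignettes/hyperpgg-methods.Rmd` | model, protocol, numerical choices, limitations |
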