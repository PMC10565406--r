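# flowscales

Human mobility is organised at multiple nested scales — neighbourhoods,
commuting basins, metropolitan regions — and these scales are visible in
origin–destination (OD) trip tables as groups of tiles within which flows
are largely contained. `flowscales` extracts those **flow communities**
from a directed, weighted mobility network in an unsupervised way, selects
the **robust scales** at which they persist, quantifies how well any
partition (data-driven or administrative) **contains** the observed flows,
and fits a **shock-response model** to temporal changes in containment,
such as those induced by a lockdown. It is aimed at quantitative
geographers, epidemiological modellers and network scientists working
with tile-level OD data.

## The methods in brief

**Mobility graph.** Daily OD records are averaged over a baseline window
into a weighted adjacency matrix `A` (self-loops, i.e. intra-tile trips,
kept in a separate vector), restricted to the largest strongly connected
component. The random walk `M = D_out⁻¹ A` with stationary distribution
`π` (solving `πM = π`) and random-walk Laplacian `L = I − D_out⁻¹A`
summarises the directed flow structure; the relative Frobenius deviation
of `ΠM` from symmetry measures how far the chain is from detailed
balance.

**Markov stability.** For a Markov scale `r` (log-scale `s = log10 r`),
the quality of a partition with indicator matrix `H` is

    Tr[ Hᵀ (Π exp(−L r) − πᵀπ) H ]

— the probability that a random walker starting at stationarity is found
in its initial community after time `r`, in excess of chance. Short
scales favour fine partitions, long scales coarse ones. The objective is
maximised by a generalised Louvain algorithm; repeating the optimisation
at each scale gives a within-scale ensemble NVI (reproducibility) and a
cross-scale NVI matrix (persistence), where NVI is the variation of
information normalised by the joint entropy. The **Block NVI** curve —
the average-pooled, smoothed diagonal of the cross-scale matrix —
defines basins; the within-scale NVI minimum of each basin is a robust
scale.

**Containment.** For a partition `H` and flow matrix `Ã = A + diag(intra)`,
`F = HᵀÃH` is the community-lumped flow matrix; community coverage
`C_k = F_kk / (F·1)_k`, partition coverage `C` (flow-weighted mean of
`C_k`), and nodal containment `NC_i` (share of node `i`'s inter-tile
outflow staying in its community) quantify how well the partition traps
mobility.

**Shock response.** Relative coverage change `ΔC(t) = (C(t) − C(t₀))/C(t₀)`
over weekly networks is fitted by the solution of
`dx/dt = −βx + αe^{−λt}`, i.e. `x(t) = α/(β−λ)(e^{−λt} − e^{−βt})`,
yielding a stimulus amplitude `α`, stimulus time `1/λ` and recovery time
`1/β` (weeks), with profile-likelihood F-test confidence intervals.

Because real tile-level OD feeds are typically proprietary, the package
ships a synthetic generator that plants a nested hierarchy of flow
communities with realistic sparsity, heterogeneity and quasi-reversibility,
plus a lockdown scenario that moves inter-community trips into self-loops
while conserving totals.

## Worked example

```r
library(flowscales)

plan  <- hierarchy_plan(levels = c(4, 4), leaf_size = 4,
                        decay = 0.1, asymmetry = 0.1)  # 64 tiles, 16-in-4 blocks
flows <- generate_hierarchical_flows(plan, seed = 7)
g     <- build_baseline_graph(flows)
#> flow_graph: 64 nodes, 4032 directed edges
#>   total inter-tile flow 3062.24, intra-tile flow 11122.2
m     <- random_walk_model(g)
#> random_walk_model: 64 states
#>   detailed-balance deviation 0.08692

scan <- scale_scan(m, markov_scales(-1.5, 1.5, 40), n_repeats = 50, seed = 7)
sel  <- select_robust_scales(scan)
#> scale_selection: 3 basins, kernel 2
#>   basin 1: indices 1..6, selected index 1 (s = -1.500)
#>   basin 2: indices 7..21, selected index 13 (s = -0.577)
#>   basin 3: indices 22..40, selected index 27 (s = 0.500)
```

Three robust scales emerge: the singleton partition at very short
Markov times, and the two planted levels — comparing against the ground
truth, the 16-community partition at `s = −0.58` and the 4-community
partition at `s = 0.5` both reach NVI = 0 against their planted level.
Containment of the fine planted partition:

```r
containment(g, attr(flows, "planted")$level_1)
#> containment_report: 16 communities
#>   coverage C = 0.9231, avg nodal containment NC = 0.6263
```

92% of all flow (intra-tile trips included) stays within the 16 fine
communities. A simulated 18-week lockdown that suppresses
inter-community trips and returns them to the origin tiles:

```r
scn    <- shock_scenario(alpha = 0.8 * abs(1/16 - 1/2),
                         beta = 1/16, lam = 1/2, n_weeks = 18)
weekly <- apply_lockdown_scenario(flows, scn, attr(flows, "planted")$level_1)
gs     <- weekly_graphs(weekly, g$nodes)
fit_shock(delta_coverage_series(gs, attr(flows, "planted")$level_1))
#> shock_fit (Delta C activation-response model)
#>   alpha = 0.02914  (95% CI 0.02914-0.02914)
#>   1/beta = 16 weeks (CI 16-16), 1/lam = 2 weeks (CI 2-2)
#>   chi2 = 1.071e-31 over 18 points
```

The fit recovers the scenario's stimulus time (2 weeks) and recovery
time (16 weeks) from the coverage series alone; on noiseless input the
residual is at machine precision, hence the degenerate intervals.

The same workflows run end-to-end from CSV inputs via `run_baseline()` /
`run_temporal()` with a `pipeline_config()`, or from the shell through
`inst/scripts/flowscales.R` (`simulate`, `baseline`, `temporal`
subcommands).

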