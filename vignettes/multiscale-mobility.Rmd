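---
title: "Multiscale flow communities in mobility networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale flow communities in mobility networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowscales)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they carry, the parameters that matter, and
the design decisions taken where the methodology leaves choices open.
Every empirical statement here is computed by the package's test suite
or acceptance script; nothing is quoted from external analyses.

## 1. The mobility graph and its random walk

The analysis object is a directed, weighted graph whose nodes are
geographic tiles and whose edge weights `A[i, j]` are average daily
trips from tile `i` to tile `j`. Intra-tile trips (self-loops) are kept
in a separate vector `intra` and excluded from `A`: they carry no
information about *between*-tile structure, but they matter for
containment statistics, where staying put counts as contained flow.

`build_baseline_graph()` averages records per ordered pair over a date
window and restricts the result to the largest strongly connected
component (LSCC). Strong connectivity is what makes the random-walk
machinery well-posed: the walk `M = D_out⁻¹A` then has a unique
stationary distribution `π` with `πM = π`, and the random-walk
Laplacian `L = I − D_out⁻¹A` generates an ergodic continuous-time
diffusion. Two conventions are deliberate:

* **Averaging with missing days.** A day in the window with no record
  for a pair contributes zero trips to that pair's mean (the window
  length is the denominator). Mobility feeds suppress low counts, so an
  absent record is best read as "no (reportable) trips", not "missing
  at random".
* **Node order.** Nodes are sorted lexicographically by tile ID, so all
  matrices, partitions and serialised artifacts are identical across
  runs and platforms.

`π` is computed by solving the dense linear system `(Mᵀ − I)π = 0` with
one balance row replaced by the normalisation `Σπ = 1`. Power iteration
is not used because periodic chains — as small as a reciprocal 2-cycle —
make it oscillate; the direct solve has no such failure mode, and a
condition-number check guards against near-singular inputs.

Two diagnostics characterise the directedness of the data:
the pairwise relative asymmetry `PRA = |A_ij − A_ji|/(A_ij + A_ji)`
per unordered pair, and the detailed-balance deviation
`‖ΠM − (ΠM)ᵀ‖_F / ‖ΠM‖_F`, which is zero exactly for reversible chains.
Empirical commuting-dominated networks sit close to reversibility
(most journeys are round trips); the synthetic generator reproduces
this regime, and its `asymmetry` parameter moves the deviation up
monotonically.

## 2. Markov stability and the generalised Louvain optimiser

The Markov stability of a partition with indicator matrix `H` at scale
`r` is `Tr[Hᵀ(Π e^{−Lr} − πᵀπ)H]`: the stationary probability that a
diffusing walker is found at time `r` in the community it started in,
minus the product-of-marginals baseline. Small `r` probes fine
structure, large `r` coarse structure; sweeping `r` produces a family
of partitions of increasing coarseness without fixing the number of
communities in advance. Directionality enters through `L` and `π`; the
quality matrix `Q(r)` itself need not be symmetric, but the trace
objective only sees `(Q + Qᵀ)/2`, which is what the optimiser uses for
move gains.

`quality_matrix()` computes `e^{−Lr}` by scaling-and-squaring
(`Matrix::expm`). The matrix is dense regardless of the sparsity of
`A`, so the implementation is deliberately dense and refuses networks
above 2000 nodes rather than silently thrash; tile-level national
networks (10²–10³ nodes) fit comfortably.

`louvain_partition()` is a generalised Louvain: sweep nodes in random
order, move each to the community with the largest positive gain,
aggregate communities by summing `Q` blocks, repeat. Design points:

* Ties in gain (including gain exactly zero) keep the node where it is,
  which guarantees termination without a tolerance dance.
* The sweep order is the only randomness; the seed fixes it.
* At `r → 0` the optimum is the all-singletons partition with quality
  `1 − ‖π‖²`; at large `r` every partition's quality tends to 0 and the
  single community (quality exactly 0, since the entries of `Q` sum to
  zero) wins. These limits are used as test oracles, alongside
  exhaustive enumeration of all 203 partitions on 6-node graphs, where
  the heuristic attains the global optimum in ≥95% of instances.

`scale_scan()` runs the optimiser `n_repeats` times per scale with
sub-seeds drawn once from the master seed. The default grid is 60
scales with `s = log10(r) ∈ [−1.5, 1.5]` — wide enough to span
singleton-to-whole-graph behaviour on networks of this size — and the
defaults are 50 repeats for routine use; 300 repeats mirrors a
full-scale study and simply costs proportionally more. The within-scale
ensemble NVI uses all pairs up to 50 repeats and a fixed seeded
subsample of 1225 pairs beyond, so the statistic's cost stays bounded
while its estimator stays deterministic given the seed.

## 3. NVI and scale selection

The normalised variation of information between partitions `p` and `q`
is `VI(p, q)/H(p, q)`: variation of information divided by joint
entropy, computed from the empirical joint label distribution with
uniform weight per node and natural logarithms (the ratio is
base-invariant). It is a metric on partitions, lies in [0, 1], and is 0
only for identical partitions; we define it as 0 when both partitions
are trivial (joint entropy 0). Node weighting is uniform rather than
flow-weighted: the statistic compares partitions as combinatorial
objects, and flow enters the analysis through the containment measures
instead.

Scale selection processes the two NVI statistics sequentially:

1. **Block NVI.** The cross-scale matrix `NVI(s, s′)` is average-pooled
   around its diagonal with half-width `k` (mean of the full
   `(2k+1)×(2k+1)` submatrix, truncated at the grid edges), then
   smoothed with a centred moving average of the same width. Using one
   width for both steps removes a free parameter. The default
   `k = max(1, ⌈m/20⌉)` scales with the grid so that pooling always
   sees a few percent of the scale axis.
2. **Basins.** Local minima of the Block NVI curve (strict neighbour
   comparison; plateau minima collapse to their central index, for
   determinism) seed basins; the watershed boundaries are the interior
   local maxima between adjacent minima, plus the grid ends. A constant
   curve yields a single basin spanning the grid — documented
   behaviour, not an error.
3. **Robust scales.** Within each basin the selected scale is the
   argmin of the within-scale ensemble NVI, with ties broken toward the
   basin's Block-NVI minimum. Basins can optionally be ranked by depth
   and truncated.

Selection depends only on the index order of the grid, never on the
numeric `s` values, so any monotone reparametrisation of the scale axis
leaves the result unchanged.

## 4. Containment statistics

With `Ã = A + diag(intra)` and lumped flows `F = HᵀÃH`:
community coverage `C_k = F_kk/(F·1)_k`; partition coverage
`C = Σ_k d̂_k C_k / Σ_k d̂_k`, identically the ratio of within-community
flow (self-loops included) to total flow; nodal containment
`NC_i = (AH)_{i,c(i)} / (A·1)_i`, the share of node `i`'s *inter-tile*
outflow staying in its community; and `NC`, its unweighted mean. The
asymmetric treatment of self-loops — included in `C`, excluded from
`NC_i` — follows the displayed definitions of the two statistics:
coverage asks "how much of all mobility is internal", nodal containment
asks "when people leave their tile, do they stay in their community".
One community gives `C = NC = 1`; all-singletons with zero intra flow
gives `C = NC = 0`; merging communities can only internalise flow, so
coverage never decreases along a coarsening chain.

`compare_to_reference()` handles reference geographies that do not
cover every tile (a routine situation with suppressed rural data) by
dropping uncovered nodes from both partitions before the NVI, with a
count. `rank_sum_compare()` wraps the two-sided Mann–Whitney test for
comparing per-community or per-node statistic distributions; fully tied
samples return `p = 1` with a degeneracy flag.

## 5. The shock-response model

Coverage responds to a mobility shock like a linear system under an
exponentially decaying stimulus: `dx/dt = −βx + αe^{−λt}`, `x(0) = 0`,
with solution `x(t) = α/(β−λ)(e^{−λt} − e^{−βt})`, and
`ΔC(t) = (C(t) − C(t₀))/C(t₀)` is fitted to it. Parameters are in
units of 1/weeks; time is measured from the series start (the baseline
week is `t = 0`). Numerical conventions:

* At `β = λ` (within 1e−9 relative) the closed form degenerates; the
  analytic limit `α t e^{−λt}` is substituted.
* The formula is symmetric under swapping `β` and `λ`, so the
  parameters are only identified up to that exchange. The fit reports
  the labelling `λ ≥ β` — stimulus faster than recovery — which is the
  physically meaningful regime for a lockdown (sharp onset, slow
  relaxation).
* Optimisation is Levenberg–Marquardt (`minpack.lm`) under the bounds
  `α ≥ 0`, `β, λ > 0`, from a deterministic 27-point grid of starts
  (amplitude scaled from the observed peak through the unit-amplitude
  response peak; stimulus times 1, 2, 4 weeks; recovery times 8, 16, 32
  weeks). The best final residual is kept, and the optimum is verified
  in tests to beat every start.
* 95% confidence intervals profile each parameter against the
  F(1, n−3) threshold, re-optimising the other two parameters at every
  profiled value. Profiling was chosen over covariance-based intervals
  because the double-exponential model is strongly curved in (β, λ)
  near the swap-symmetry ridge, where a quadratic approximation is
  unreliable. A Monte-Carlo study in the acceptance tests (200 noisy
  replicates, σ = 0.002) checks that the α interval's coverage lies in
  a calibrated band.

## 6. The synthetic generator: what it emulates and what it does not

The generator plants a nested hierarchy: `levels = c(4, 4)` with
`leaf_size = 4` gives 64 tiles in 16 fine blocks inside 4 superblocks.
The expected rate between two tiles is `within_rate · decay^d`, where
`d` counts the hierarchy levels separating them, multiplied by mean-one
log-normal noise shared by the two directions, then perturbed per
direction by a mean-one log-normal factor of scale `asymmetry`.
Defaults and their reasoning:

* `within_rate = 10`, `intra_rate = 200`: keeps intra-tile trip mass a
  few times the inter-tile mass, the regime of tile-level mobility
  feeds where most activity never leaves a tile.
* `decay = 0.1`: an order of magnitude per level gives clearly nested
  flow communities without making recovery trivial.
* `sigma = 0.5`: the hierarchy itself already produces an edge-weight
  coefficient of variation near 2.8 at this geometry; mild per-pair
  dispersion lands the overall CV in the 2.5–3.5 band typical of
  empirical tile networks. Larger `sigma` mainly blurs the planted
  structure without changing the qualitative regime.
* `asymmetry = 0.1`: produces detailed-balance deviations of a few
  percent to ~10%, i.e. quasi-reversible flows, as observed for
  commuting-dominated mobility.
* `sparsity = 1` by default at these sizes; when sparsified, strong
  connectivity is restored by a directed ring within any fragmented
  fine block and, if needed, a minimal-weight directed ring over the
  fine blocks — the downstream analysis requires an LSCC, and the
  repair uses the smallest sampled weight so it cannot distort the
  planted structure.
* Trips are real-valued: baselines represent day-averages, which are
  non-integer in real feeds too.

The lockdown scenario multiplies inter-community trips (with respect to
a designated planted level, default the finest, since empirical
lockdowns contract mobility toward fine scales) by `1 − g(t)`, where
`g(t)` is the activation-response shape clipped to `[0, 1)`, and adds
the removed trips to the **origin** tile's self-loop, conserving weekly
totals exactly. The origin-side reassignment is a declared modelling
choice: suppressed journeys are treated as not taken, so their mass
stays where the traveller lives. Nothing in the empirical record pins
down the redistribution side; users who prefer a destination-side or
split rule can post-process the weekly tables.

What the generator does **not** emulate: geographic embedding and
distance-decay kernels, population-size heterogeneity across tiles,
day-of-week seasonality, reporting noise and suppression thresholds of
real feeds, and tiles appearing/disappearing over time. Passing tests
on synthetic data therefore demonstrates the correctness and internal
consistency of the algorithms under a controlled generative model — not
that any particular empirical network has recoverable scales.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance script use 64-tile two-level and
81-tile three-level networks, scans of 40 scales × 50 repeats, and
200-replicate Monte-Carlo studies — sizes chosen so the full pipeline
(including the exhaustive 6-node Louvain oracle at 500 instances) runs
in minutes on a single core while still exercising every code path at
meaningful scale. All randomness flows from explicit seeds: the scan
derives per-(scale, repeat) sub-seeds from its master seed once, so
results are bitwise reproducible, and rerunning any workflow with the
same seed regenerates byte-identical artifacts.

## 8. Known limitations

* Dense `e^{−Lr}` limits networks to ~2000 nodes; very large OD feeds
  need coarser tiling first.
* Louvain is a heuristic; the ensemble-NVI machinery measures (and the
  selection exploits) its variability, but individual partitions carry
  no optimality certificate.
* The shock model is linear with a single exponential stimulus;
  multi-wave interventions need a sum of such terms, which the package
  does not fit.
* NVI compares hard partitions only; no overlapping or fuzzy community
  support.
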