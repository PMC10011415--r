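---
title: "Critical-mass contagion on hypergraphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-mass contagion on hypergraphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercontagion)
```

This vignette documents the model implemented by **hypercontagion**, the
numerical methods behind each module, and the design decisions and
limitations a user should know before trusting the output.

## 1. The model

A hypergraph has `N` nodes and hyperedges $e_j$, node subsets with
cardinality $|e_j| \ge 2$. Node states are binary (active/inactive) and
evolve in continuous time:

* every active node deactivates at rate $\delta$;
* every hyperedge whose active-member count $T_j$ has reached its
  **critical mass** $\Theta_j = \lceil \Theta^* |e_j| \rceil$ runs a
  Poisson process at rate $\lambda_j = \lambda\,\lambda^*(|e_j|)$; when it
  fires, *all* inactive members of $e_j$ activate at once. When
  deactivations push $T_j$ back below $\Theta_j$ the process is destroyed.

The cardinality modulation $\lambda^*$ is injectable
(`dynamics_params(modulation = ...)`). The default is
$\lambda^*(c) = \log_2 c$, which is 1 at $c = 2$: restricted to its
pairwise hyperedges the model *is* the standard SIS epidemic on a graph
(each cardinality-2 hyperedge is simulated as two directed infection
processes, for which a threshold of one active member is automatic).
`modulation_constant()` expresses the other case used throughout the
package: a hyperedge with a bare, cardinality-independent rate.

The all-inactive state is absorbing, so long-run behaviour is studied
quasi-stationarily (Section 3). The two summary statistics are the order
parameter $\rho = \langle n \rangle / N$ and the susceptibility
$\chi = (\langle n^2\rangle - \langle n\rangle^2)/\langle n\rangle$ of
the active count $n$.

## 2. Stochastic simulation

`simulate_contagion()` is a statistically exact event-driven simulation.
The scheduler is the **next-reaction method**: every live process
(one deactivation clock per active node, two directed infection clocks
per pairwise edge with an active source, one group clock per
above-threshold hyperedge) holds an exponentially distributed absolute
firing time in an indexed binary heap. Clocks are created and destroyed
as the state changes; since all clocks are exponential, discarding and
redrawing on creation is statistically equivalent to the classical
time-rescaling bookkeeping but simpler. The core is C++ with a PCG32
generator, so a run is fully determined by the integer `seed`.

A second, independent scheduler (the direct/rate-sum method) is kept in
the test-suite to cross-validate the event law; the two agree in
distribution (Kolmogorov–Smirnov test on absorption times).

The event log records, for every event, its time, kind, hyperedge, the
set of flipped nodes and the resulting active count; trajectories can be
replayed exactly, which the tests exploit (conservation checks,
`node_activity()` replay).

## 3. Quasi-stationary sampling

`run_qs()` conditions the process on survival with the stored-states
method: a list of `M` previously visited active configurations is
maintained, the current state overwrites a uniformly chosen slot at rate
`p_r` per unit time, and whenever the absorbing state is reached it is
replaced by a uniform draw from the list. After a relaxation time `t_r`,
the time-weighted occupancy distribution of $n$ is accumulated in
adaptive windows of length `t_s`; sampling stops when $\chi$ changes by
less than `eps` between consecutive windows, or after `c_max` windows.
Defaults (`M = 100`, `p_r = 0.02`, `t_r = 1e4`, `t_s = 1e3`,
`eps = 1e-3`, `c_max = 500`) are conventional QS practice; the estimates
are insensitive to `M` and `p_r` over a wide range (tested), and the
time scales should be reduced for small systems.

`find_peaks()` locates modes of the occupancy profile (moving-average
smoothing plus a prominence criterion) — bimodality is the signature of
intermittent switching between metastable activity levels.
`lambda_sweep()` runs a grid of spreading rates from multiple initial
seedings and labels statistical branches per grid point by
single-linkage clustering of $\rho$ (split at gaps larger than $5/N$,
re-merge clusters closer than three pooled standard errors). Distinct
branches under different seedings indicate multistability.

## 4. Mean field

The individual-based (first-order) closure treats node states as
independent Bernoulli variables with activation probabilities $y_i$:

$$\dot y_i = -\delta y_i + (1 - y_i) \sum_{e_j \ni i} \lambda_j\,
P\!\left(\Theta_j \le K_j^{(i)} \le |e_j| - 1\right),$$

where $K_j^{(i)}$ is the number of active members of $e_j$ other than
$i$ — a **Poisson-binomial** variable. Its pmf is evaluated through the
discrete Fourier transform of its characteristic function
(`poisson_binomial_dft()`, C++), which stays numerically stable for
group sizes in the hundreds; the exponential-cost subset enumeration
(`poisson_binomial_enum()`, refused above 20 trials) serves as the
exactness oracle.

`integrate_steady()` finds steady states with Runge–Kutta–Fehlberg 4(5)
(per-step tolerances `atol = 1e-4`, `rtol = 1e-3`) in growing time
chunks. A subtlety: the accepted local error of an adaptive solver puts
a noise floor of roughly the step tolerance on the achievable residual
$\max_i |\dot y_i|$, far above the steady-state criterion of $10^{-8}$.
Integration therefore only runs the *approach* phase — which also
selects the dynamically stable state reachable from the initial
condition — and once the residual is below $10^{-2}$ a damped Newton
iteration on $\dot y = 0$ (forward-difference Jacobian) polishes the
root. The polish is accepted only if it reaches the target residual
without moving any coordinate by more than 0.1, so it refines the fixed
point the flow selected rather than jumping to a different one.

`branch_continuation()` maps multistable branch structure: relax a seed
micro-state at one grid value of $\lambda$, then march the grid up and
down re-using the previous steady state as the initial condition; a
direction stops when its trace collapses onto an already-recorded branch
or fails to converge.

## 5. The hyperblob and its exact chain

`make_hyperblob(N, k)` builds a uniform random simple $k$-regular graph
(pairing model with restart; the complete graph is constructed
deterministically when $k = N - 1$, since rejection sampling would never
hit the unique $(N-1)$-regular graph) plus one hyperedge containing all
$N$ nodes. Node-permutation symmetry collapses the dynamics onto a
birth–death chain over the active count $n$ with one extra jump:

* births $\beta_n = \mathrm{lam}_k\, n (N - n)/N$ (pairwise spreading,
  with $\mathrm{lam}_k = \lambda \langle k \rangle$ the lumped drive),
* deaths $\delta n$,
* a jump $n \to N$ at bare rate $\lambda^*$ for
  $\theta \le n \le N - 1$ (the global hyperedge fires).

The QS constraint zeroes the $1 \to 0$ transition. `blob_stationary()`
computes the stationary distribution with an $O(N)$ forward recursion
obtained by accumulating the balance equations across the cut between
$n$ and $n + 1$; every term in that rearrangement is positive, so the
recursion is cancellation-free, and overflow is avoided by periodic
rescaling. The result is verified against the full stationarity
equations ($\max |Q^\top \pi|$), and an independent SVD null-space route
(`blob_nullspace()`) is provided as an oracle; both are compared in the
tests, along with the closed-form product solution available when
$\lambda^* = 0$.

**Annealed vs. quenched.** The drive $n(N-n)/N$ counts active–inactive
pairs as if the regular layer were re-drawn at every instant. For a
sparse quenched layer this is an approximation (good, but detectable at
high Monte-Carlo precision); it is *exact* when the pairwise layer is
complete with per-edge rate $\mathrm{lam}_k/N$, because then the
active–inactive edge count is exactly $n(N - n)$ and symmetry makes $n$
Markov. The simulator-vs-chain validation test therefore uses the
complete layer, and a separate loose-tolerance test documents the sparse
approximation. `blob_dynamics()` maps chain parameters onto simulator
parameters.

`scaling_analysis()` quantifies the hybrid character of the transition:
for each system size it locates the edges of the lower-to-upper jump on
a `lam_k` grid (both from the order parameter and from the extrema of
$d\chi/d\mathrm{lam}_k$) and fits the window width to $N^{-\mu}$. A
hybrid transition combines a discontinuous jump with sub-linear window
scaling $\mu < 1$. The transition point itself moves with $N$, so the
grid must bracket the jump at *all* requested sizes; sizes where the
grid fails to resolve the window are flagged and excluded from the fit.

## 6. Generators and realism

`make_community_hypergraph()` splits nodes into equal blocks; each block
receives its own hyperedges, and `m_out` *bridge* hyperedges each span
exactly two uniformly chosen blocks with a uniform split of members
between the two sides. Cardinalities are exponential with mean `mu`,
discretised by ceiling and clamped into `[2, N/n_c]`, and duplicate
hyperedges are resampled. The bridge count controls the coupling between
communities: with few bridges, the weakly-connected community can hold a
different activity level than the strong one for a long time
(multistability under different seedings); with many bridges, single
runs alternate between the levels (intermittency, bimodal occupancy
distribution). Both regimes are exercised in the test-suite at reduced
system size; the crossover bridge counts are size-dependent, so they
were located empirically for the tested `N`.

`rewire_configuration_model()` implements vertex-labeled
configuration-model shuffling (pool two hyperedges, repartition into the
original cardinalities; reject on within-hyperedge repeats or duplicate
hyperedges), preserving the membership-count sequence and cardinality
multiset — the standard null model for higher-order structure.

## 7. Reproducibility machinery

All stochastic entry points take an explicit integer seed; generators
restore the caller's RNG state, and the C++ engine uses its own PCG32
stream, so results are reproducible across sessions and platforms.
`run_experiment()` maps a flat key-value configuration to a result
bundle (TSV/JSON plus a manifest echoing the resolved configuration and
package version); identical configurations produce byte-identical
outputs. The CLI script (`inst/cli/hypercontagion.R`) is a thin wrapper:
config-file values are overridden by flags, which are overridden by
trailing `key=value` arguments, and stochastic methods refuse to run
without a seed unless `--no-seed` is explicit.

A small exact example:

```{r blob-example}
p <- blob_params(N = 100, lam_k = 1, lam_star = 5, theta_star = 0.2)
st <- blob_stationary(p)
str(chain_summary(st))
```

## 8. Limitations

* **Mean-field bias.** The first-order closure ignores dynamical
  correlations; its steady states are approximations whose quality
  varies with structure and parameters. Use it for branch structure and
  qualitative diagrams, not for quantitative prevalence.
* **Annealed chain.** As discussed in Section 5, the occupancy chain is
  exact only for the complete pairwise layer; for sparse layers it is an
  approximation.
* **QS estimates are Monte-Carlo.** Near transitions, branch lifetimes
  can exceed any fixed sampling budget; `lambda_sweep()` results should
  be read with the replica scatter (and, where relevant, multiple
  seedings) in mind.
* **Peak detection** depends on the smoothing window and prominence
  threshold; for small systems the defaults may merge close modes.
* **Scaling analysis** requires the grid to resolve the jump at every
  size; the `resolved` flag must be checked before trusting the fitted
  exponent.
* Hyperedges of cardinality 1 are dropped at construction (the dynamics
  gives them no role), and the edge-list file format cannot represent
  isolated nodes — round-tripping a hypergraph through disk keeps all
  hyperedges but may drop isolated nodes unless `n` is supplied on
  reload.
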