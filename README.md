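# hypercontagion

Critical-mass contagion dynamics on hypergraphs: an exact-event stochastic
simulator with quasi-stationary sampling, an individual-based mean-field
ODE solver with branch continuation, structured hypergraph generators, and
an exact Markov-chain analysis of the "hyperblob" that exhibits hybrid
phase transitions.

## The model

A hypergraph consists of `N` nodes and hyperedges `e_j` — node subsets of
arbitrary cardinality `|e_j| >= 2`. Each node is either active or
inactive. The continuous-time dynamics has two kinds of transitions:

- **Deactivation.** Every active node independently becomes inactive at
  rate `delta`.
- **Group activation with a critical mass.** A hyperedge whose number of
  active members has reached its threshold `Theta_j = ceiling(Theta* |e_j|)`
  carries a Poisson process at rate `lambda_j = lambda * lambda*(|e_j|)`;
  when it fires, *all* inactive members of the hyperedge activate
  simultaneously. The default modulation `lambda*(c) = log2(c)` equals 1
  at cardinality 2, so the pairwise skeleton of the hypergraph runs the
  standard SIS epidemic model, and group interactions are increasingly
  (but sublinearly) amplified.

This threshold mechanism generates phenomenology absent from graphs:
discontinuous (hybrid) transitions, multistability between activity
branches selected by the initial condition, and intermittent switching
between metastable activity levels, visible as bimodal state
distributions.

Because the all-inactive state is absorbing, stationary properties are
measured with the quasi-stationary (QS) method: the process is conditioned
on survival by replacing visits to the absorbing state with previously
stored active configurations. Summaries are the order parameter
`rho = <n>/N` and the susceptibility `chi = (<n^2> - <n>^2)/<n>`, whose
peaks locate transitions.

## What the package provides

| Area | Functions |
|---|---|
| Hypergraph core | `hypergraph()`, `load_hypergraph()`, `write_hypergraph()`, `projected_adjacency()`, `giant_component()`, `restrict_to_nodes()` |
| Dynamics | `dynamics_params()`, `hyperedge_threshold()`, `hyperedge_rate()`, `modulation_log2()`, `modulation_constant()` |
| Simulation | `simulate_contagion()` (next-reaction scheduler in C++), `node_activity()` |
| QS sampling | `qs_config()`, `run_qs()`, `qs_summary()`, `find_peaks()`, `lambda_sweep()` |
| Mean field | `poisson_binomial_enum()`/`poisson_binomial_dft()`, `ode_rhs()`, `integrate_steady()`, `branch_continuation()` |
| Exact hyperblob chain | `blob_params()`, `blob_generator()`, `blob_evolve()`, `blob_stationary()`, `blob_nullspace()`, `chain_summary()`, `blob_dynamics()`, `scaling_analysis()`, `fit_scaling_exponent()` |
| Generators | `make_hyperblob()`, `make_community_hypergraph()`, `rewire_configuration_model()` |
| Experiments | `run_experiment()`, `read_config()`, and the CLI script in `inst/cli/` |

## Worked example

A *hyperblob* is a random k-regular graph plus one hyperedge containing
every node. Its permutation symmetry collapses the dynamics onto a
one-dimensional occupancy chain that can be solved exactly, which makes it
the ideal benchmark: the same system can be studied by exact linear
algebra and by stochastic simulation.

```r
library(hypercontagion)

# exact quasi-stationary distribution of the occupancy chain
p <- blob_params(N = 200, lam_k = 0.9, lam_star = 10, theta_star = 0.2)
st <- blob_stationary(p)
unlist(chain_summary(st)[c("rho", "chi", "P_lower", "P_upper")])
#>          rho          chi      P_lower      P_upper
#> 9.149663e-01 1.270347e+00 1.650722e-05 9.999835e-01

# stochastic QS simulation of a matching hyperblob (sparse k = 6 layer)
H <- make_hyperblob(200, 6, seed = 1)
d <- run_qs(H, blob_dynamics(p, k = 6), init = 1.0, seed = 2,
            qs = qs_config(t_r = 200, t_s = 200, c_max = 20))
d
#> QS state distribution over N = 200 nodes: rho = 0.9140, chi = 1.332 (9 windows, converged)
```

The simulated order parameter (0.914) lands on the exact chain value
(0.915). (For a sparse pairwise layer the chain is an annealed
approximation; it becomes exact for the complete layer, see the vignette.)

The hybrid character of the transition shows up in finite-size scaling:
the width of the `lam_k` window over which the order parameter jumps
shrinks as `N^-mu` with `mu < 1`, instead of being either zero
(classical first order) or trivially sharp:

```r
scaling_analysis(Ns = c(200, 400, 800, 1600),
                 lam_k_grid = seq(0.4, 1.3, by = 0.005),
                 lam_star = 10, theta_star = 0.2)
#> Finite-size scaling of the hyperblob transition window
#>     N lam_rho_lo lam_rho_up lam_chi_lo lam_chi_up width_rho width_chi resolved
#>   200      0.635       0.80     0.6425     0.7175     0.165     0.075     TRUE
#>   400      0.800       0.91     0.8075     0.8525     0.110     0.045     TRUE
#>   800      0.915       0.99     0.9225     0.9525     0.075     0.030     TRUE
#>  1600      0.995       1.04     1.0025     1.0175     0.045     0.015     TRUE
#> mu (order-parameter width) = 0.618 +/- 0.029
#> mu (susceptibility width)  = 0.755 +/- 0.058
```

## Command-line interface

Every experiment is also reachable through a thin CLI wrapper around
`run_experiment()`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hypercontagion.R", package = "hypercontagion"))')" \
    blob-exact --out results n=200 lam_k=0.9 lam_star=10 theta_star=0.2
```

Subcommands: `generate`, `simulate`, `run-qs`, `sweep`, `run-ode`,
`blob-exact`; shared flags `--config`, `--out`, `--seed`, `--no-seed`,
`--log-level`. Values in `--config` files are overridden by flags, which
are overridden by trailing `key=value` pairs. Stochastic methods refuse
to run without a seed unless `--no-seed` is given. All outputs are plain
TSV/JSON plus a `manifest.json` echoing the resolved configuration.

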