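# pgsnet

Why do additive polygenic scores (PGS) predict some complex traits well and
others poorly, and why do they transfer so unevenly across populations?
`pgsnet` studies these questions in a setting where the genotype-to-phenotype
map is fully known: phenotypes are generated by simulated gene regulation
networks (GRNs) with nonlinear dynamics, and the additive statistical model is
fit to populations of such networks. Because the generative mechanism is in
hand, the gap between statistical prediction and mechanistic causation can be
measured exactly.

The package is aimed at quantitative geneticists and systems biologists who
want a controlled sandbox for questions about genetic architecture, epistasis,
the omnigenic core/peripheral picture, and PGS portability.

## The model

**Dynamics (Wagner model).** A network of N genes (default N = 10) carries a
signed weight matrix W drawn from a directed Erdős–Rényi model (each
regulation present with probability c, weights ~ N(0, 1), no self-loops).
Expression states evolve by the synchronous map

    g_i(t+1) = f( Σ_j w_ij g_j(t) ),    f(x) = 2 / (1 + e^(−a x)) − 1,

with steepness a = 10, from a random ±1 initial state, until a fixed-point
equilibrium g\* is reached (iteration cap 100). The **phenotype** of a network
is the mean of its equilibrium expression, y = mean(g\*); the number of
iterations to equilibrium is its **path length**.

**Genetic variation.** A population (default P = 10⁴ individuals) shares the
reference topology; each individual's weight on edge (j→i) is drawn from
N(w_ij, s.d.), with s.d. a fraction (default 10%) of |w_ij|. The individual's
phenotype is computed from the shared initial state.

**Polygenic score.** A LASSO regression y = Gβ + ε of phenotype on the I
individual edge weights, with the penalty chosen by 5-fold cross-validation;
the reported R² is out-of-fold.

**Dissection of predictability.**

- *Local stability*: the Jacobian J_ij = f′(h\*_i) w_ij at equilibrium; its
  spectral radius and count of zero eigenvalues diagnose the local dynamical
  regime, and the per-edge one-step response f′(h\*_i) g\*_j predicts the top
  PGS effect sizes.
- *Global sensitivity*: Sobol first-order (S0ᵢ) and total (STᵢ) indices of
  the phenotype with respect to each edge weight, estimated by Saltelli A/B/Cᵢ
  sampling (default N_sobol = 5×10⁴). εTᵢ = STᵢ − S0ᵢ is the edge's
  non-additive (epistatic) share; the sums (S0, εT) place a network in the
  **additive space**, and S0 ≈ the PGS R² when the network operates in its
  linear regime.
- *Connection classes*: core (STᵢ > 0.01, S0ᵢ ≥ εTᵢ), peripheral
  (STᵢ > 0.01, S0ᵢ < εTᵢ), remote (STᵢ ≤ 0.01).
- *Complexity*: two-component positive feedbacks (w_ij w_ji > 0), density,
  clustering, path length, with permutation enrichment tests across network
  ensembles.
- *Transferability*: R² of a PGS applied to populations from other variation
  regimes or from single-edge mutant networks, related to a spectral graph
  distance between the mutant and wild-type weight matrices.

## Worked example

```r
library(pgsnet)

sel <- select_converging_network(10, 0.3, seed = 7)   # network + fixed point
sel$trajectory
#> <trajectory_result> converged after 4 iterations; phenotype -0.7648; psi 1.09e-01

pop <- build_population(sel$network, variation_spec(0.1), pop_size = 10000,
                        initial_state = sel$initial_state, seed = 2)
pop
#> <population> 10000 individuals x 28 edges; 100.0% converged; phenotype sd 0.004554

fit <- fit_pgs(pop, seed = 3)
fit
#> <pgs_fit> 28 edges (17 non-zero beta); lambda 7.24e-06; CV R2 0.973 (in-sample 0.973)

sob <- network_sobol(sel$network, variation_spec(0.1), sel$initial_state,
                     n_sobol = 10000, seed = 4)
sob
#> <sobol_result> 28 inputs, n = 10000; additive sum S0 = 0.980; non-additive sum epsT = 0.034

class_ratios(classify_edges(sob))
#> # A tibble: 1 × 3
#>   core_ratio peripheral_ratio remote_ratio
#>        <dbl>            <dbl>        <dbl>
#> 1     0.0714           0.0357        0.893

local_stability(sel$network, sel$trajectory$equilibrium)
#> <stability_report> spectral radius 0.0189; 2 zero eigenvalue(s) of 10
```

Reading: this network reaches equilibrium in 4 steps; at 10% weight variation
its population phenotype is well predicted by the additive score (CV R² 0.97),
consistent with the Sobol additive sum S0 = 0.98 and the tiny non-additive
share εT = 0.03 — a near-linear network whose few core edges (7% of
connections) carry the signal, while 89% of connections are remote. Networks
with large εT behave very differently: their R² collapses and peripheral
connections dominate (see `run_ensemble()` and the vignette).

Higher-level drivers: `run_single_network()` (full per-network bundle with
plain-text artifacts), `run_ensemble()` (additive-space table + enrichment
tests), `run_variation_sweep()` (cross-regime transfer matrix),
`mutant_screen()` (single-edge mutant transferability). `tidy()`/`glance()`
methods and `plot_additive_space()` / `plot_transfer_matrix()` /
`autoplot()` cover tabulation and figures.

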