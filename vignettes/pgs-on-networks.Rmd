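---
title: "Polygenic scores on simulated gene regulation networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores on simulated gene regulation networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsnet)
```

`pgsnet` asks a mechanistic question about a statistical object: when a
phenotype is *generated* by a nonlinear gene regulation network, how much of
it can an *additive* polygenic score capture, and what does the network's
structure and dynamics tell us about the answer? This vignette documents the
model, every tunable parameter, the numerical choices, and the design
decisions that were genuinely open — together with what the simulation does
and does not say about real data.

## The generative model

### Networks

A reference genotype is a signed, weighted, directed graph on `n_genes`
(default 10) genes: each of the N(N−1) ordered pairs carries a regulation
independently with probability `connect_prob`, and present weights are i.i.d.
standard normal (`generate_reference_network()`). No self-loops. We store W
in "incoming" orientation — row i collects the regulations *received* by
gene i — so one update step is the matrix expression `g(t+1) = f(W g(t))`.
File exports state this convention in their header comment.

The connectivity of the ensembles analysed here defaults to `c = 0.3`. This
value is a modelling choice: it yields sparse-but-connected 10-gene networks
whose median number of two-component positive feedbacks is ~2, a regime in
which both strongly additive and strongly epistatic networks arise at useful
frequencies. It is exposed everywhere as a parameter.

### Dynamics

Expression evolves synchronously under the sigmoid
`f(x) = 2/(1 + exp(−a x)) − 1 = tanh(a x / 2)` with steepness `a = 10`
(`sigmoid()`, computed via `tanh` for overflow-free saturation). Initial
states are random ±1 vectors (each gene fully on or off with probability
1/2). The phenotype is the mean equilibrium expression.

**Convergence criterion.** We iterate until the one-step sup-norm change
`max_i |g_i(t) − g_i(t−1)|` falls to `conv_tol = 1e-4` (cap `max_iter = 100`
updates; trajectories that hit the cap are flagged non-converged). The
equilibrium is reported as the *pre-update* state of the firing step, which
makes the fixed-point residual `max_i |g*_i − f(Σ_j w_ij g*_j)|` equal to
the observed change, hence ≤ `conv_tol` *by construction* — a guarantee a
windowed average cannot give. A trailing-window mean-absolute-change score
(`psi_score()`, window `conv_window = 10`) is computed and reported for every
trajectory and can be selected as the criterion (`criterion = "psi"`); we
chose the sup-norm default because the residual guarantee is what every
downstream linearisation relies on, and because a mandatory 10-step window
would misreport trivially fast equilibria (an empty network reaches its fixed
point in one step). Path lengths are therefore comparable only within one
criterion.

**Why the strict open interval (−1, 1) is closed in practice.** `tanh`
saturates to exactly ±1.0 in double precision for |a x/2| ≳ 19. States can
thus sit numerically *on* the boundary; all code treats [−1, 1] as the valid
range.

### Populations

`build_population()` perturbs each non-zero reference weight independently:
individual weight ~ N(w_ij, sd), with `sd = sd_fraction · |w_ij|` in
`"relative"` mode (default) or `sd = sd_fraction` in `"absolute"` mode. The
relative reading matches "variation given by a percentage of the wild-type
weight"; the absolute mode is provided because a fixed s.d. per edge is the
other natural convention, and the two differ materially for small weights.
Zero entries stay zero — the population shares one topology — and all
individuals start from one shared initial state, so phenotypic variance is
purely genetic. Default `pop_size = 1e4`, `sd_fraction = 0.1`.

Individuals that fail to converge within the cap keep their capped state as
phenotype and *remain in the population* (`n_converged` reports the count):
dropping them would condition the genotype distribution on dynamical
behaviour and bias the regression design.

## The statistical model

`fit_pgs()` fits `y = Gβ + ε` by LASSO (`glmnet`), predictors standardised
internally, coefficients reported on the weight scale. The penalty grid is
glmnet's 100 log-spaced values down to 1e-4 of the null-model penalty; the
5-fold cross-validation *minimum* is used (no one-standard-error rule — we
want the best-predicting penalty, not the sparsest acceptable one). The
reported R² is out-of-fold (prevalidated), an honest estimate of prediction
in unseen individuals; the in-sample value is stored alongside and the two
nearly coincide at P = 10⁴, I ≤ 90. Fold assignment is seeded and stored.

## Dissecting predictability

### Local stability

At the equilibrium the dynamics linearise to `J_ij = f′(h*_i) w_ij`,
`f′(x) = (a/2)(1 − f(x)²)`. Saturated genes (|h*| large) yield near-zero
Jacobian rows, producing the characteristic mixture of near-zero eigenvalues
(neutral directions) and sub-unit eigenvalues (decaying directions);
`stability_summary()` counts eigenvalues with modulus ≤ `zero_tol = 1e-6`
(dense real weights make exact zeros arise only through saturation; the
tolerance is configurable). A spectral radius ≥ 1 at a converged point is a
warning, not an error: convergence within 100 steps does not strictly imply
local contraction.

The per-edge *local effect score* is `s_ij = f′(h*_i) g*_j`, the derivative
of one update of gene i with respect to w_ij — an outer product masked to
the support. The aggregate matrix–vector product J g\* is exposed alongside
(`local_effect_scores()$jg`) since the construct "Jacobian times steady
state" admits both readings; the per-edge form is the one that aligns with
per-edge PGS effect sizes.

### Global sensitivity

`network_sobol()` treats the phenotype map (edge weights → equilibrium mean
expression from the fixed initial state) as a black box over the population's
weight distribution and decomposes its variance. Sampling follows the
Saltelli A/B/Cᵢ scheme with *plain* pseudo-random normal draws (no
quasi-random sequence — the sampled object is the population distribution
itself): two independent n × k matrices A, B, and for each edge i the radial
matrix Cᵢ = A with column i replaced from B; n(k+2) model evaluations total.
Each of A and B has the full `n_sobol` rows (the "half of the sample" reading
in which the 2k-column draw is split columnwise).

With this Cᵢ convention the estimators are, after centring all outputs by
the pooled mean f0 (centring leaves expectations unchanged but removes
f0-amplified Monte-Carlo noise — essential here, where |f0| can exceed the
output s.d. by orders of magnitude):

- first-order: `S0_i = mean(y_B (y_Ci − y_A)) / V`
- total (Jansen): `ST_i = mean((y_A − y_Ci)²) / (2V)`

with V the pooled-sample variance. These are the standard low-variance forms
for this design; their correctness is enforced in the test suite against
analytic oracles (an additive Gaussian model, where S0ᵢ = aᵢ²σᵢ²/V exactly,
and y = x₁ + x₂x₃, where S0 = (½, 0, 0) and ST = (½, ½, ½)). Per-index
standard errors come from the sample spread of the estimator terms. Negative
Monte-Carlo estimates are *never clipped* — clipping would bias the sums that
define the additive space — and `eps = st − s0` is exact by construction.
Non-converged evaluations follow the population policy (capped state,
counted). `replicates > 1` repeats the scheme and reports means with
between-replicate standard errors.

`sobol_indices()` refuses zero-variance outputs rather than returning
indeterminate ratios.

### Connection classes, complexity, transferability

Edges are classified from their indices: **core** (STᵢ > 0.01 and
S0ᵢ ≥ εTᵢ, ties to core), **peripheral** (STᵢ > 0.01, S0ᵢ < εTᵢ),
**remote** (STᵢ ≤ 0.01, boundary included). The 1% threshold is the
conventional "contributes more than 1% of phenotypic variance" cut and is a
parameter. A `clamp_eps` flag floors negative εTᵢ estimates at zero for
sensitivity analysis; the default consumes raw values.

Complexity metrics: two-component positive feedbacks (pairs with
w_ij w_ji > 0 — two repressions also form a positive loop), density
I/(N(N−1)), and the clustering coefficient of the undirected unweighted
support. The mean *local* clustering coefficient is the default (isolated
and degree-1 genes contribute 0), with global transitivity available — the
informal definition "probability that neighbours of a node are connected"
is ambiguous between the two, and they differ on hub-like graphs.
Enrichment of any measure in the high-εT group (above the ensemble's 80th
percentile) is tested by permutation with the add-one correction,
one-sided (greater), so the smallest attainable p is 1/(n_perm + 1).

Transferability applies a fitted PGS to populations from other conditions.
In `run_variation_sweep()` each row of the transfer matrix is normalised by
the training condition's R² on a *fresh* test population at the training
s.d. — both numerator and denominator are then out-of-population quantities,
and the diagonal normalises to exactly 1. `mutant_screen()` redraws one
uniformly chosen edge weight from N(0, 1) per mutant (support unchanged),
scores the wild-type PGS on a fresh population around the mutant, and
annotates each mutant with the spectral distance
`d(G₁,G₂) = Σᵢ (|λᵢ(G₁)| − |λᵢ(G₂)|)²` (moduli sorted descending; the
unrooted sum as printed — a `rooted` option gives the Euclidean form, and
group comparisons are invariant to the choice since the map is monotone).
Mutants with transfer R² ≤ 0 (ties included) are "non-transferable"; the
groups are compared by a one-sided Wilcoxon rank-sum test on spectral
distances.

## What the generator does and does not emulate

The synthetic populations capture: a shared regulatory topology with
continuous individual variation in interaction strengths, purely genetic
phenotypic variance, epistasis arising mechanistically from the dynamics
(saturation and state flips) rather than being injected statistically, and
ensembles in which additive and non-additive architectures coexist.

They deliberately omit: allele-frequency spectra and discrete genotypes,
linkage disequilibrium, environmental variance, selection, and any network
evolution. Passing tests therefore demonstrate properties of the
*mechanism-to-statistics* pipeline — e.g. that the additive Sobol mass equals
the PGS R² in linear regimes, or that non-transferable mutants are
spectrally distant — not calibration against human GWAS data, where the
omitted ingredients matter.

A note on the **linear-regime fixtures** used by several tests: in this
model, global contraction forces the trivial equilibrium g\* = 0 (the map is
odd), whose "phenotypic variation" is pure convergence-tolerance noise. A
meaningful linear regime is instead *local*: a saturated equilibrium whose
Jacobian spectral radius is small and whose population, at the studied
variation level, contains no state flips. Test fixtures select such networks
by exactly that criterion (radius < 0.05 and no flips in a probe population
at 5% variation).

## Problem sizes and numerical choices

Simulation sizes in the test suite and the acceptance script are scaled to
the information each check needs: Sobol oracle checks at n = 5×10⁴ (the
full-scale base sample), network Sobol runs at n = 3–10×10³, populations of
1–2×10³, ensembles of 12–20 networks, 50-mutant screens. These choices give
Monte-Carlo standard errors comfortably inside the asserted tolerances while
keeping any single run in minutes on one CPU; all defaults in
`experiment_config()` remain at full scale (P = 10⁴, N_sobol = 5×10⁴,
100 networks, 200 mutants), with `profile = "test"` switching to the scaled
set. The batched fixed-point iteration that dominates the Sobol sweep
(n(k+2) ≈ 1.5×10⁶ trajectories at full scale) is implemented in C++ and
tested for exact agreement (to summation-order rounding) with the reference
R implementation.

Other numerical decisions: the sigmoid is evaluated as `tanh`, stable for
any input; the Jacobian uses the closed-form derivative (validated against
central finite differences at 1e-7 to relative error < 1e-6); TSV artifacts
print 17 significant digits so text round-trips are lossless; JSON summaries
round-trip at full double precision; all stochastic stages draw their seeds
from one master seed through named independent streams, so full pipeline
outputs are byte-identical across reruns.

## Known limitations

- Only fixed-point attractors are analysed; limit cycles and multistability
  beyond the reached attractor are out of scope (non-converged individuals
  are retained with capped states, which slightly blurs phenotypes in
  heavily oscillatory regions of weight space).
- Sobol index estimates for strongly flip-driven networks are heavy-tailed:
  a handful of flipped samples can dominate the variance, so sums can move
  noticeably between replicates at moderate n; the per-index standard errors
  quantify this and `replicates` averages over it.
- The core/peripheral/remote classification consumes raw Monte-Carlo
  estimates; near the 1% threshold, class ratios inherit sampling noise.
- Path length is criterion-dependent and only comparable within one
  convergence criterion.
- N = 10 genes throughout; nothing in the implementation restricts N, but
  the reported regimes (e.g. connectivity 0.3, feedback medians) are
  specific to small networks.
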