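---
title: "Modeling function diversity and specialization in growing systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling function diversity and specialization in growing systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcdiv)
```

## The model

Complex adaptive systems — a bacterial cell expressing proteins, a federal
agency hiring staff, a city absorbing workers — grow by the arrival of
individuals, and their repertoire of distinct *functions* (protein species,
occupation categories) grows with them. `funcdiv` implements a generalized
Yule–Simon process for this growth. The state is the abundance vector
$\{k_i\}$, one positive count per existing function, with system size
$N = \sum_i k_i$ and diversity $D$ = number of functions. Each arriving
individual either

* **innovates** — creates a new function of abundance 1 — with probability
  $$p = \min\!\Big(1,\; \frac{p_0}{\sum_{i=1}^{D} k_i^{\theta}}\Big),$$
* or **joins** an existing function $i$, chosen by nonlinear preferential
  attachment
  $$q_i = \frac{k_i^{\gamma}}{\sum_{j=1}^{D} k_j^{\gamma}}.$$

The process is Markovian: both probabilities depend only on the current
abundance distribution.

Three parameters, with interpretations:

* `p0` (innovation scale, default 1, dimensionless) absorbs environmental
  effects assumed constant within a class of systems. In the mean-field
  logarithmic regime it is exactly the semi-log slope `b` (below), so
  empirically meaningful values range from order 1 (microbes, agencies) to
  order 100 (city occupation systems).
* `theta` (diversification exponent) sets *what* suppresses innovation:
  $\theta = 0$ gives $p = p_0/D$ — richness alone suppresses novelty;
  $\theta = 1$ gives $p = p_0/N$ — total mass suppresses it, i.e. large
  functions inhibit new ones most. Negative values (abundance *promotes*
  innovation) are permitted with a warning.
* `gamma` (specialization exponent) sets the concentration of growth:
  $\gamma = 0$ spreads newcomers uniformly over functions, $\gamma = 1$ is
  linear preferential attachment (equivalent to copying the function of a
  uniformly chosen individual), and $\gamma > 1$ is superlinear, leading to
  gelation — one function absorbs nearly all growth — which is why the
  constructor warns there.

### Mean-field limits

With $dD/dN = p$, two limits solve in closed form
(`mean_field_diversity()`):

* $\theta = 0$: $dD/dN = p_0/D \Rightarrow D(N) = \sqrt{D_0^2 + 2p_0(N-N_0)}$,
  i.e. Heaps-law growth with exponent $1/2$ at large $N$;
* $\theta = 1$: $dD/dN = p_0/N \Rightarrow D(N) = D_0 + p_0\ln(N/N_0)$,
  i.e. logarithmic growth.

General $\theta$ has no closed form and is handled by simulation. For
$\theta = 1$ the model also has an *exact* finite-$N$ mean: the innovation
indicator at pre-arrival size $n$ is Bernoulli$(\min(1, p_0/n))$,
independent across arrivals, so from $(N_0, D_0) = (1, 1)$,
$\mathbb{E}[D(N)] = 1 + \sum_{n=1}^{N-1}\min(1, p_0/n)$. The test suite
uses this as an exact oracle (note it is $1 + H_{N-1}$ for $p_0 = 1$, not
$H_N$: the innovation probability is evaluated on the pre-arrival state).

```{r meanfield}
mean_field_diversity(0, p0 = 1, n0 = 1, d0 = 1, n = 1e4)
mean_field_diversity(1, p0 = 1, n0 = 1, d0 = 1, n = 1e4)
```

## Simulation engine

`simulate_growth()` advances one individual at a time. The attachment
weights $k_i^\gamma$ live in a Fenwick (cumulative-weight) tree, giving
$O(\log D)$ weight updates and inverse-CDF sampling per arrival; the
running sums $\sum k_i^\theta$ and $\sum k_i^\gamma$ are updated
incrementally and refreshed by full recomputation every
`rebuild_every = 10^4` arrivals to bound floating-point drift (the
accumulated relative drift over $10^5$ arrivals with rebuilds disabled is
below $10^{-9}$; a test checks this). A run of $10^5$ arrivals takes on
the order of 10 ms, so ensembles of 50–100 replicates at $N = 10^5$ are
interactive.

Numerical and design choices worth knowing:

* **Clamp.** $p_0/\sum k_i^\theta$ can exceed 1 for the earliest arrivals
  of a small system (e.g. $p_0 = 1$, state `[1]`); `p` is clamped to 1 so
  it remains a probability. Only the first few arrivals are affected.
* **Degenerate `p0 = 0`** is allowed and gives a pure-attachment process
  (no innovation ever); useful for testing the attachment kernel in
  isolation.
* **Overflow** of $k^\theta$ (extreme exponents) raises an error naming
  the offending count and exponent rather than propagating `Inf`.
* **Seeds.** Every stochastic operation takes an explicit integer seed.
  Ensembles derive replicate seeds deterministically via
  `child_seed(master, r)`, so a single master seed reproduces an entire
  ensemble bitwise.
* **Initial state** defaults to one function with one individual (`[1]`);
  calibration instead starts from an observed small system (below).
* **Checkpoints** default to 20 per decade of $N$, log-spaced.

## Rank-frequency analysis and the calibration distance

`compute_rank_frequency()` sorts abundances in decreasing order (stable
sort: ties keep input order) and normalizes by $N$, giving
$f_r = k_{(r)}/N$. Distributions are compared in log space at matched
integer rank:

$$\mathrm{dist}(a, b) = \sqrt{\tfrac1R \sum_{r=1}^{R}
  \big(\log_{10} f_{a,r} - \log_{10} f_{b,r}\big)^2}
  \;+\; w\,\big(\log_{10} D_a - \log_{10} D_b\big)^2,$$

with $R = \min(D_a, D_b)$ common ranks. "Log space" here means log of
*frequency* at matched rank (the log-frequency axis of rank-abundance
plots), base 10. Two open choices were resolved as follows and are
deliberate package conventions:

* **Unequal diversities** are handled by truncation to common ranks
  *plus* the additive diversity penalty (weight $w$, default 1). Pure
  truncation would let a low-diversity simulation match a high-diversity
  target spuriously on the few ranks it has; the penalty restores
  sensitivity to $D$, which is the quantity $\theta$ chiefly controls.
  With $w = 0$ the distance is a metric on the common-rank truncation.
* **Replicate averaging** (`ensemble_mean_rank_frequency()`) is done in
  $\log_{10}$-frequency space at fixed rank, truncated to the minimum
  replicate diversity, with the profile's effective diversity taken as
  the geometric mean of replicate diversities — both consistent with the
  log-space objective.

## Calibration

`calibrate()` estimates $(\hat\theta, \hat\gamma)$ for an observed
abundance table by minimizing the distance between the observed
rank-frequency distribution and the ensemble-mean profile of simulations
grown from a small initial state to the observed $N$. Conventions:

* `p0` is fixed at 1 during calibration (a class-level constant, not a
  per-entity parameter); a 3-parameter mode (`calibrate_p0 = TRUE`) is
  available behind a flag.
* The initial state should be a lesser-size system of the same family
  (the recovery harness uses a size-100 snapshot of the target's own
  trajectory).
* The optimizer is differential evolution, DE/rand/1/bin with
  per-generation dithered $F \in [0.5, 1]$ and $CR = 0.9$, over the
  bounded box $\theta \in [-1, 2]$, $\gamma \in [0, 1.5]$ by default;
  population 20, generation cap 60, early stop when the population's loss
  spread falls below `tol = 1e-3`. Out-of-box mutants are reflected back
  inside, so no candidate is ever evaluated outside bounds.
* The objective is stochastic, so all candidates within a run share the
  same per-replicate simulation seeds (common random numbers), a standard
  variance-reduction that also makes the reported loss bitwise
  reproducible from $(\hat\theta, \hat\gamma,$ seed$)$.
* Objective evaluations average `replicates = 10` simulations in
  log-frequency space.

`recovery_experiment()` wraps this in a parameter-recovery harness:
generate synthetic targets at known $(\theta, \gamma)$, optionally
perturb their counts with multiplicative log-normal noise, calibrate, and
report bias and RMSE. On noiseless targets of size $N = 10^4$ the
per-cell median absolute error (5 repeats) stays within 0.15 for both
parameters across $\theta \in \{0, 0.5, 1\}$, $\gamma \in \{0.4, 0.8\}$ —
the acceptance suite recomputes exactly this. $\theta = 1$ cells are the
noisiest: there $D(10^4) \approx 11$, so a single target realization
carries substantial diversity noise, which the median over repeats
absorbs.

## Scaling fits and model selection

`fit_power_law()` fits $D = D_0 N^{\beta}$ by OLS of $\log_{10} D$ on
$\log_{10} N$ (the standard Heaps'-law estimator), with a t-based 95% CI
on $\beta$; `fit_logarithmic()` fits $D = b\ln N + c$ by OLS on the
semi-log scale. The **natural log** is the deliberate convention for the
logarithmic law: under exponential population growth
$N(t) = N_0 e^{\alpha t}$ it gives linear-in-time diversity
$D(t) = \alpha b\,t + D_0$, so the diversity growth rate is the product
$\alpha b$ (`urban_diversity_growth_rate()`; e.g. $\alpha = 0.0071$,
$b = 128$ gives $0.9$ new occupations per year — a consistency check on
the base convention, since base-10 would be off by $\ln 10$).

Because $R^2$ from different response transforms cannot be compared,
`compare_scaling_models()` refits both laws by least squares on the
natural $D$ scale (the power law via Levenberg–Marquardt, started from
the log-log estimate) and selects by AIC; non-convergence of either fit
makes the selection abstain. CIs are OLS t-intervals and are labeled as
such; bootstrap intervals are out of scope.

## Synthetic fixture families

`generate_fixture_family()` emulates the *shape* of the empirical
datasets this model family is aimed at: a class of systems spanning
several orders of magnitude in size (default $10^2$–$10^5$, 10 sizes per
decade), each with a concave, roughly exponential-in-rank abundance
distribution. All systems of a family are snapshots of one growth
trajectory, so larger systems genuinely contain the smaller ones —
consistent with the modeling assumption that large systems arise by
sequential addition of individuals to small ones. Optional measurement
noise is multiplicative log-normal on counts (default log-sd 0.1),
rounded with floor 1, which preserves positivity, diversity, and the
concave shape.

Default generating scales were chosen once, to match the diversity
magnitudes such classes exhibit: power-law-regime families ($\theta = 0$)
use $p_0 = 1$, giving $D(10^5) \approx 450$, typical of occupation
counts in large organizations; logarithmic-regime, city-like families
($\theta = 1$) use $p_0 = 128$ — the mean-field identity $b \equiv p_0$
ties the innovation scale to the empirically fitted city slope — giving
$D(10^5) \approx 10^3$, typical of metropolitan occupation repertoires.
This choice also matters statistically: at $p_0 = 1$ a $\theta = 1$
trajectory reaches only $D \approx 12$ by $N = 10^5$ and a *single*
stochastic path of that size is not reliably classifiable as logarithmic
versus power-law by any criterion — its fluctuations dominate the
curvature difference. City-scale $p_0$ makes the regimes cleanly
separable, and the model-selection acceptance check (200 independent
noisy families) passes at 100% in both regimes.

What the generator does **not** emulate: cross-system heterogeneity in
$(\theta, \gamma, p_0)$ within a family (all snapshots share one
parameter set and one trajectory), independent system histories,
classification-scheme artifacts, and function obsolescence or individual
departures. Passing tests on these fixtures therefore demonstrates
correctness of the machinery under the model's own assumptions, not that
real systems obey the model.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own verification conditions: analytic-limit
ensembles use 40–50 replicates at $N = 3\times10^3$–$10^5$; the
attachment-kernel checks use $10^5$ draws per state; recovery uses the
full $3\times2$ grid at $N = 10^4$ with 5 repeats per cell; model
selection uses 100 families per regime. The full suite runs in roughly
ten minutes on one core.

## Known limitations

* No removal of individuals and no function obsolescence; growth only.
* Markovian dynamics only — no memory of past states.
* Innovation conflates de-novo creation with adoption/diffusion of
  functions existing elsewhere.
* The calibration objective compares abundance *shape* and diversity at a
  single final size; it does not use intermediate time points.
* Whether real systems clamp $p \le 1$ early in growth is unobservable at
  the sizes where it matters; the clamp is a modeling convention.
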