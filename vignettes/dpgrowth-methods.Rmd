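---
title: "Modelling adolescent drinking trends with a Dirichlet-process mixture of growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent drinking trends with a Dirichlet-process mixture of growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpgrowth)
```

## The problem

The HBSC school survey has asked 15-year-olds about their drinking habits
every four years since 1985/86. The resulting country-level prevalences of
weekly-or-more alcohol use form a heavily unbalanced panel: 40
countries/regions, up to nine survey waves each, with countries joining
late, skipping waves, and (after a 2017/18 questionnaire change) only 23
countries reporting the final comparable wave. `dpgrowth` models such panels
to (i) estimate smooth per-country trends, (ii) group countries whose trends
are indistinguishable, and (iii) project the next survey wave.

## The model

For country $i$ at wave $j$ with scaled time $u_{ij}$, observed prevalence
(in percent) is modelled as

$$y_{ij} = \alpha + f(u_{ij}) + g_i(u_{ij}) + \epsilon_{ij}, \qquad
  \epsilon_{ij} \sim N(0, \tau_\epsilon^{-1}),$$

where $f(u) = \sum_{d=1}^{n}\beta_d u^d$ is a global degree-$n$ polynomial
trend and $g_i(u) = \sum_d b_{id}\, u^d$ a country-specific polynomial
deviation. The random-effect vectors $b_i$ receive a Dirichlet-process
prior,

$$b_1,\dots,b_m \mid F \sim F, \qquad F \sim DP(c, F_0), \qquad
  F_0 = N(0, \tau_b^{-1} I),$$

whose almost-sure discreteness ties groups of countries to a common $b$
vector: the *clusters*. Countries with similar trend shapes co-cluster and
borrow strength from each other, which is what makes estimation possible for
countries observed in as few as three waves. Priors: effectively flat
Gaussians (sd $10^3$) on $\alpha$ and $\beta$; independent Gamma(0.1, 0.1)
on the precisions $\tau_\epsilon$ and $\tau_b$; $c \sim$ Gamma($a$, 1),
whose shape $a$ encodes the prior expected number of clusters through
$E[K \mid c] = \sum_{i=1}^{m} c/(c+i-1)$ (`prior_expected_clusters()`).

Two structural readings deserve comment, because the printed form of such
models is often ambiguous and both are implemented:

* **Random basis without an intercept (default).** The random basis is
  $(u, \dots, u^n)$, the same powers as the fixed part. Clusters then
  separate by trend *shape*, not by level, and the fitted per-country
  trajectories are near-cluster-level curves. On the shipped panels this
  yields a handful of clusters per gender (modal $K \approx 5$–6 for boys,
  2–3 for girls, with one dominant cluster of about two dozen countries for
  girls) — the coarse, interpretable clusterings such analyses report. With
  `model_config(random_intercept = TRUE)` an intercept column is prepended
  and clusters also separate by level; the same panels then fragment into
  10–12 level-sorted clusters. The intercept variant is the natural choice
  for synthetic recovery studies whose clusters are level-shifted, and is
  what the package's own recovery tests use.
* **Isotropic base measure (default).** $F_0$ carries one shared precision
  $\tau_b$ across coefficient dimensions, matching its scalar-precision
  statement; `shared_tau_b = FALSE` gives each dimension its own
  Gamma-distributed precision instead. On the shipped panels the two give
  similar posteriors.

## Time scale

Wave labels ("2013/14") denote a school year; the later calendar year is the
survey year (2014), which is how results for these waves are cited. Scaled
time is $u = (\text{year} - 2002)/16$, so the nine waves sit at
$u = -1, -0.75, \dots, 1$ and the forecast wave 2021/22 at $u = 1.25$. The
centring keeps the monomial basis well conditioned without orthogonal
polynomials; both constants are configurable in `time_mapping()`.

## Sampler

`run_mcmc()` is a systematic-sweep Gibbs sampler (C++ core, R's RNG, so a
seed makes runs bit-identical):

1. **Cluster labels** — Chinese-restaurant-process full conditionals with
   instantiated effects (Neal's Algorithm 2): an existing cluster is weighted
   by its size times the Gaussian likelihood of the country's residual
   vector under that cluster's effect; a new cluster by $c$ times the
   marginal likelihood with the effect integrated analytically over $F_0$.
   Emptied clusters are pruned; labels are canonicalised by first
   appearance.
2. **Cluster effects** — Gaussian full conditionals pooling member
   countries.
3. **Fixed effects** — joint Gaussian update of $(\alpha, \beta)$.
4. **Precisions** — Gamma full conditionals ($\tau_\epsilon$ from the
   residuals; $\tau_b$ from the current cluster effects).
5. **Concentration** — the Escobar–West auxiliary-variable (Beta/Gamma
   mixture) update.

Defaults follow the protocol of the source analysis: 100,000 iterations with
30,000 burn-in, a single chain per gender; retained draws are thinned by 10
(a package choice; 7,000 retained states are ample for the co-clustering and
predictive summaries used). Initialisation is deterministic: one cluster,
zero effects, moments from the pooled panel.

Correctness is tested against independent oracles rather than by eye: exact
enumeration of all set partitions on a 3-series panel (co-clustering
frequencies to three decimals), 1-D quadrature of the concentration's
conditional posterior, closed-form Gaussian/Gamma conjugacy checks, and a
Geweke-style successive-conditional simulation whose parameter marginals are
compared to plain prior sampling with autocorrelation-corrected standard
errors (naive batch errors understate the uncertainty badly here — the
intercept's integrated autocorrelation time approaches 100).

## Posterior summaries

* `cosim_matrix()` — pairwise co-clustering frequencies.
* `point_partition()` — the sampled partition minimising the least-squares
  distance to the similarity matrix (Dahl's criterion), ties to the earliest
  draw. A caveat documented by the tests: on diffuse posteriors this
  criterion retains more clusters than the posterior modal $K$ — ambiguous
  pairs (co-clustering probability near 0.5) are split. The modal $K$ from
  `k_distribution()` is the better single number for "how many clusters";
  the point partition is the better display of who belongs together.
* `posterior_predictive()` / `forecast_wave()` — per-draw trajectory values
  $\alpha + f(u) + g_i(u)$ at any wave, including the unobserved 2021/22;
  reported means are clamped to $[0, 100]$ (the sampler itself never
  clamps — the likelihood is an unbounded Gaussian on the percent scale).
* `holdout_validation()` — absolute errors against one wave's observations.
  The default `method = "estimate"` fits the full panel and evaluates the
  fitted trajectories at that wave, the convention behind the published
  per-country error tables this package reproduces; `method = "masked"`
  blanks the wave before fitting, giving true out-of-sample extrapolation
  errors. The two answer different questions and differ a lot here: polynomial
  trends extrapolate poorly one wave beyond the data (masked-mode errors are
  roughly twice the in-sample ones and can collapse to the 0% boundary),
  which is worth knowing before trusting any single-wave-ahead forecast.

## Synthetic data

`generate_panel()` simulates the generative model exactly: a cubic
rise-then-fall global trend (default $\alpha = 35$, $\beta = (-4, -8, 4)$ on
the scaled-time basis), three clusters as level shifts $(+15, 0, -15)$ on
the intercept-bearing random basis, Gaussian noise of 3 percentage points,
and staggered-entry missingness mimicking the survey (each series enters at
a random wave and is observed from then on, never with fewer than three
waves — the survey's own inclusion rule). These defaults keep every
trajectory comfortably inside the percent scale; unclipped noise can still
stray outside $[0, 100]$, which is left as-is by default (with a warning
path) because the model itself is unbounded.

What the generator does *not* emulate: binomial sampling noise with
country-specific denominators (the real survey's per-country sample sizes
are not public in the tables used), questionnaire changes, or
heteroscedasticity. Passing recovery tests on these panels therefore
validates the inferential machinery, not the adequacy of the Gaussian
homoscedastic likelihood for real survey data.

## Problem sizes used in tests

The shipped test suite runs reduced chains chosen to keep the full suite in
the low minutes while leaving every conclusion stable across seeds: 10k–30k
iterations for fixture-panel checks, 2k-iteration fits across 20 seeds for
partition recovery (adjusted Rand $\ge 0.9$ in $\ge 18/20$ seeds), 12k
sweeps for the enumeration comparison, and an 8k-step Geweke chain. The
acceptance script (`scripts/acceptance.R`) always runs the full 100k/30k
protocol.

## Known limitations

* Prevalences are modelled as unbounded Gaussians on the percent scale; no
  logit transform, no binomial variant, no survey weights.
* Countries are equally weighted regardless of sample size.
* A single chain per gender; convergence monitoring is limited to the
  log-likelihood trace and seed-to-seed comparison.
* One-wave-ahead extrapolation inherits the stiffness of global polynomials;
  forecasts for countries far from their cluster's trajectory (sparse,
  erratic series such as Bulgaria's three non-consecutive waves) carry
  errors an order larger than the typical country's.
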