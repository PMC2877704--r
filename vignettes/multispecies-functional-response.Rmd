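---
title: "Fitting multispecies functional responses to delivery-count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting multispecies functional responses to delivery-count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfr)
```

## The scientific problem

A generalist predator's effect on any one prey species cannot be read off
a single-species functional response: time spent handling alternative
prey depresses consumption of the focal prey, and density-dependent
attack (switching) reshapes mortality at low density. `msfr` implements
the full chain needed to quantify this from field data: a multispecies
functional response (MSFR) model, a count observation model, a Bayesian
sampler, predictive checks, and a graphical equilibrium analysis.

The package is built around a hen-harrier-type system: three prey (red
grouse chicks, meadow pipits, field voles), densities recorded as
prey-specific indices, diet recorded as deliveries to the nest over
watched hours at a handful of site-year combinations.

## Model and assumptions

Consumption of prey $i$, in items per hour per (individual) predator:

$$F_i = \frac{a_i N_i^{m_i}}{1 + \sum_j a_j t_j N_j^{m_j}}$$

Assumptions worth stating explicitly:

* **Densities are indices.** Each $N_j$ is in its own field units
  (chicks·km⁻², pipits·km⁻¹, voles per 100 trap-nights). The attack
  coefficient $a_j$ absorbs the unknown proportionality between index and
  true abundance, which is why we never interpret $a_j$ as an encounter
  rate or compare it across prey, and why no unit conversion is
  attempted. The true-encounter-rate and index-proportional formulations
  collapse to the same algebra; only $a$ is carried.
* **$m_j \ge 1$ by construction.** $0 < m < 1$ would mean attack rates
  that *fall* as a prey becomes more abundant with everything else held
  fixed, which is biologically implausible; the type constructor rejects
  it, and the prior puts zero mass there.
* **No observation error in densities**, and counts are conditionally
  independent given the parameters — their dependence enters only through
  the shared handling-time denominator.
* **No numerical response.** Predator density is a scenario constant;
  aggregative settlement of predators is out of scope.

The observation model is negative binomial in the NB2 parameterisation,
$\mathrm{Var}(Y) = \mu + \mu^2/k$ with $\mu = F_i \times$ effort. NB2 was
fixed as a deliberate choice (several NB parameterisations exist; none is
canonical in the source literature for this model), with one dispersion
$k$ per prey by default and a `shared_k` switch for a single pooled
dispersion.

## Priors

| parameter | prior | default hyperparameters |
|---|---|---|
| $a_i$ | gamma | mean 1, variance 0.99 (relatively uninformative) |
| $t_i$ | gamma | mean 2 h, variance 2 |
| $m_i$ | shifted gamma, min 1 | mean 2, variance 0.9 (95th pct $\approx$ 3.9) |
| $k_i$ | gamma | mean 1, variance 10 (weakly informative) |

All priors are moment-parameterised (`shape = (mean − shift)²/var`,
`scale = var/(mean − shift)`) and individually replaceable. Two defaults
deserve justification:

* **Handling-time prior.** Field-derived prey-specific hyperparameters
  are not available to the package; gamma(mean 2 h, var 2) reflects that
  any prey item must be flown back to the nest regardless of size, making
  handling times of a couple of hours plausible for all three prey. They
  are echoed in all output metadata and overridable.
* **Joint prior on $(a, m)$ for the focal prey.** Observational
  attack-rate data could in principle induce a joint prior; no such data
  ship with the package, and a fabricated reconstruction would masquerade
  as information. The default is independent priors plus an
  `extra_log_prior` hook through which a user can supply any joint term.

## Sampler

Component-wise (systematic-scan) Gaussian random-walk Metropolis–Hastings.
Choices, and why:

* **Proposal scales:** $\log a$, $\log t$, $\log(m-1)$, $\log k$, with
  the Jacobian in the acceptance ratio. Parameters span six orders of
  magnitude ($a_{\text{grouse}} \sim 10^{-3}$ vs $a_{\text{vole}} \sim
  4$); log-scale steps make one step-size meaningful everywhere and keep
  every stored draw inside the support automatically. Component-wise
  updates are what makes *per-parameter* acceptance-rate tuning
  well-defined.
* **Adaptation:** every 500 burn-in iterations, any parameter whose block
  acceptance rate falls outside 15–30% has its step multiplied or divided
  by 1.5. Steps freeze at the end of burn-in, so the retained chain is a
  valid time-homogeneous Markov chain (detailed balance holds exactly
  after burn-in).
* **Scale:** defaults are a desk-scale 50,000 retained draws after a
  10,000-draw burn-in (about a minute for 30 site-years on one CPU).
  Production runs in the millions of iterations are purely a
  configuration change.
* **Initialisation** at the prior means, overridable.
* **Overflow guard:** a proposal extreme enough that $N^m$ overflows a
  double (e.g. $m > 500$ during early, untuned burn-in) returns
  $-\infty$ and is rejected, rather than aborting the run; a NaN from any
  other source still aborts with the iteration index, since that would
  indicate a genuine defect.
* **Credible intervals** use R's default type-7 quantile rule; the
  convention is pinned in a test so interval endpoints are reproducible
  across environments.

Convergence is monitored the way long single-chain runs classically are:
cumulative-mean series per parameter, with a flag that the last 10% of
the series stays within a relative band (default 2%) of the final mean.
Multi-chain diagnostics (Gelman–Rubin and relatives) are deliberately out
of scope.

## Posterior predictive check

For each observed count the predictive CDF is averaged over thinned
posterior draws. Counts are discrete, so the probability integral
transform is *randomized*: a uniform draw on
$[\mathrm{CDF}(y-1), \mathrm{CDF}(y)]$, with its own seed, separate from
the sampler's. Under a correct model the PIT values are exactly uniform;
the package returns per-cell values, sorted QQ pairs against uniform
quantiles, and the Kolmogorov–Smirnov distance. The test suite verifies
both directions: uniformity when data are simulated from the fitted
model, and extreme-concentration when overdispersed data are fitted as
near-Poisson.

## Equilibrium analysis and the predator pit

Per-capita predation mortality,

$$M(N) = \text{predator density} \times \text{effort scale} \times
\frac{F_{\text{focal}}(N)}{N},$$

is intersected with logistic recruitment $r(1 - N/K)$. Roots of
$g(N) = \text{recruitment} - M$ are located by a 2,000-point grid scan
plus bisection to relative tolerance $10^{-8}$; stability follows from
the sign of $g$ on either side (stable iff growth below, decline above).
Exact grid zeros without a sign change are reported as *tangential* and
excluded from the pit predicate. A **predator pit** is operationalised
as: at least three interior equilibria with the lowest one stable —
matching the classical picture of a stable low-density state, an unstable
threshold, and a stable high-density state. The posterior pit probability
resamples parameter draws from the chain (with replacement, seeded) and
reports the fraction producing a pit.

Scenario constants that the field data cannot pin down, fixed once and
documented:

* **`effort_scale` = 336 h·season⁻¹** (8 hunting hours/day × 42-day chick
  season): converts an hourly consumption rate to the seasonal time base
  of recruitment. No canonical value exists; every output embeds the
  value used.
* **`per_pair_multiplier` = 1**: delivery rates are fitted per observed
  individual parent while pit scenarios discuss pairs; rather than
  hard-coding either reading, the conversion is an explicit knob.
* **`r` = 1 season⁻¹** as the default maximum per-capita recruitment —
  a display-scale choice putting recruitment and seasonal mortality on
  comparable axes, not an estimate. Pit probabilities are therefore
  *scenario-conditional*; the package makes no claim to reproduce any
  particular published pit probability, and the pit logic is tested on
  constructed curves with known equilibrium structure.
* **Near zero density**, $F/N \to 0$ for $m > 1$ and $\to a\,\times$
  constants for $m = 1$; the grid starts at $K \times 10^{-6}$ rather
  than 0, where the mortality index is undefined.
* `K` defaults to 208 chicks·km⁻², the predator-free equilibrium used
  throughout the grouse scenarios; harrier density defaults to the
  study-typical 0.16 pairs·km⁻².

A structural consequence of the fitted parameters worth knowing: with the
realistic parameter set (`table1_msfr_params()`), the *peak* of the
grouse mortality curve under scarce alternative prey (2 pipits·km⁻¹, 0.1
voles·htn⁻¹) is about twice its value at intermediate alternative-prey
densities (9, 1) — and roughly three times its value when alternative
prey are abundant (20, 4). The "about half" contrast that the test suite
asserts is the scarce-vs-intermediate one; the suppression at the
abundant scenario is stronger still, and the tests assert that ordering
separately.

## The synthetic-data generator

The generator emulates the *statistical structure* of the motivating
study: 11 site-years by default; grouse 5–208 chicks·km⁻², pipits 2–20
km⁻¹, voles 0.1–4 per 100 trap-nights, drawn independently and uniformly
(log-uniform optionally); watch effort 50–400 h per site-year; counts
negative-binomial around rate × effort. The default truth is the
realistic multispecies parameter set, with dispersion $k = 5$ per prey —
moderate overdispersion ($\mathrm{Var} \approx \mu + \mu^2/5$), a fixed
documented choice since no fitted dispersion is available to copy.
Effort per site-year is likewise invented (only "thousands of hours" in
total is known).

What a green end-to-end test does establish: with generous synthetic
data (30 site-years, ~500 watch hours) the sampler recovers all twelve
parameters within three posterior SDs, interval coverage over 20
replicate worlds is ~90%, and replicate-averaged log-scale RMSE of
$(a, t, m)$ falls monotonically as site-years grow 5 → 30 → 150. What it
does not establish: robustness to anything the generator omits — density
measurement error, prey misidentification at the nest, correlated prey
densities across moors (a correlation knob exists but defaults to 0),
predator aggregation, or model misspecification of the response form
itself.

## Numerical notes and limitations

* The NB→Poisson limit is exact at `k = Inf` (the code switches to the
  Poisson pmf) and agrees with the Poisson log-pmf to $10^{-6}$ by
  $k = 10^{10}$; at $k = 10^8$ the genuine NB–Poisson gap is still
  $\sim 10^{-5}$ in log-pmf, which is a property of the distributions,
  not an implementation error.
* A single-dataset RMSE comparison across data sizes is dominated by
  realization luck (a 150-site-year world can, for one seed, fit worse
  than a 30-site-year one); the shrinking-error property is therefore
  asserted on replicate-averaged RMSE.
* `write_msfr_csv` prints doubles at 17 significant digits so that
  write → read round-trips are bit-exact.
* Equilibrium counts are generically odd or even according to the
  boundary signs of $g$; a tangential contact (curve touching without
  crossing) breaks the count but is flagged rather than silently
  classified.
* The model-comparison question (which response form fits best) is out
  of scope, as are ratio-dependent response variants and time-explicit
  prey dynamics.
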