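# msfr: Bayesian multispecies functional response models

`msfr` fits the functional response of a generalist predator — how its
per-capita consumption rate of each prey species depends on the densities
of *all* its prey — to field counts of prey deliveries, and propagates the
fitted uncertainty into a graphical equilibrium analysis of the focal
prey's dynamics. The motivating system is hen harriers (*Circus cyaneus*)
on UK grouse moors delivering red grouse chicks, meadow pipits and field
voles to their nests, observed over a small number of moor-year
combinations; the package ships a synthetic-data generator emulating that
study design so the whole pipeline runs without any field data.

It is aimed at quantitative ecologists who need functional-response
parameters (and honest uncertainty on them) from sparse observational diet
data — for wildlife management questions such as whether generalist
predation can trap a prey species at low density (a "predator pit").

## The model

Consumption of prey *i* (items per hour per predator) follows the
generalised Holling form with a shared handling-time budget:

```
F_i = a_i N_i^{m_i} / (1 + Σ_j a_j t_j N_j^{m_j})
```

* `N_j` — density index of prey *j* (each in its native field units:
  chicks·km⁻², pipits per km of transect, voles per 100 trap-nights);
* `a_j` — attack-rate coefficient (absorbs index-proportionality
  constants);
* `t_j` — handling time in hours per item, so `1/t_j` is the asymptotic
  consumption rate of prey *j*;
* `m_j` — shape exponent: `m = 1, t = 0` gives a linear (Type 1) response,
  `m = 1, t > 0` the hyperbolic Type 2 disc equation, `m > 1` a sigmoidal
  Type 3 response in which preference shifts towards abundant prey
  (switching).

Observed delivery counts are modelled as negative binomial (NB2,
`Var = μ + μ²/k`) around `μ = F_i × watch hours`, with gamma priors on
`a`, `t`, `k` and a shifted-gamma prior (minimum 1, mean 2, variance 0.9)
on `m`. The joint posterior is sampled by a component-wise random-walk
Metropolis–Hastings algorithm with per-parameter proposal tuning to a
15–30% acceptance band during burn-in.

Downstream, per-capita predation mortality `F/N` (scaled by predator
density and seasonal hunting effort) is intersected with logistic
recruitment `r (1 − N/K)`: intersections are prey equilibria, classified
stable/unstable by the sign of net growth on either side, and a predator
pit is three interior equilibria with the lowest one stable. Resampling
the posterior chain gives the posterior probability of such a pit.

## Worked example

```r
library(msfr)

truth  <- default_truth()                      # realistic 3-prey parameters
design <- generate_design(design_spec(seed = 1))   # 11 site-years
obs    <- simulate_counts(design, truth, seed = 2)
obs
#> msfr_data: 11 site-years, 3 prey ( grouse, pipit, vole )
#> total deliveries: 902

fit <- fit_msfr(obs, config = sampler_config(n_iterations = 20000,
                                             burn_in = 5000, seed = 3))
summarize_chains(fit)
#>    parameter   mean     sd    lower  upper
#> 1   a_grouse 0.0172 0.0672 3.38e-05  0.128
#> 2    a_pipit 1.0569 0.7279 1.76e-01  3.026
#> 3     a_vole 2.0179 1.2707 3.78e-01  5.243
#> 4   t_grouse 3.0631 0.8793 1.38e+00  4.879
#> 5    t_pipit 2.3938 0.8789 9.38e-01  4.375
#> 6     t_vole 3.0570 1.8204 4.24e-01  7.237
#> 7   m_grouse 1.9972 0.4415 1.17e+00  2.882
#> 8    m_pipit 1.2575 0.2099 1.01e+00  1.764
#> 9     m_vole 1.2577 0.2260 1.01e+00  1.847
#> 10  k_grouse 3.5164 2.4605 7.60e-01 10.276
#> 11   k_pipit 2.7726 1.6978 7.83e-01  7.014
#> 12    k_vole 3.9787 3.8635 7.18e-01 14.471
```

Eleven site-years are sparse: the posterior means land near the truth
(e.g. handling times 2.74/1.676/2.32 h, `m_grouse` 2.51) but with wide 95%
intervals — the point of the Bayesian fit is that this uncertainty is
explicit and carried downstream. A posterior predictive check and the
equilibrium analysis then read:

```r
posterior_predictive_pit(fit, obs, seed = 4)$ks
#> [1] 0.1807  # KS distance of the randomized PIT values from uniformity

sc <- scenario(c(pipit = 2, vole = 0.1))       # scarce alternative prey
find_equilibria(truth$params, sc, recruitment_model(r = 1, K = 208))
#> equilibria (predator pit: FALSE )
#>          N stability     residual
#> 1 186.3036    stable 1.387779e-17

pit_probability(fit, sc, recruitment_model(r = 1, K = 208),
                n_draws = 200, seed = 5)$probability
#> [1] 0.035
```

With maximum recruitment `r = 1` season⁻¹ and harriers at 0.16 pairs·km⁻²,
this particular mortality surface stays below recruitment except near the
carrying capacity `K = 208` chicks·km⁻², so the grouse equilibrium sits
just below `K` and few posterior draws produce a pit. Lower `r`, higher
predator density, or more strongly sigmoidal draws move the system towards
the three-equilibrium (pit) regime; see the methods vignette
(`vignettes/multispecies-functional-response.Rmd`) for how these scenario
constants are chosen and what they mean.

The pipeline stages are also scriptable: `cmd_simulate()`, `cmd_fit()`,
`cmd_ppc()`, `cmd_equilibria()` read a JSON/YAML run configuration and
write CSV/JSON artifacts with full seed + config provenance, and
`inst/scripts/msfr-pipeline.R` dispatches them from a shell.

## Acceptance script

`scripts/acceptance.R` recomputes the package's deterministic headline
quantity — the 95th percentile of the moment-matched shifted-gamma prior
for the shape exponent (minimum 1, mean 2, variance 0.9) — by running the
installed package's quantile function, and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
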