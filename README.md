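# gambiaedyn

Stage-structured population dynamics of *Anopheles gambiae* s.l. — the
principal malaria vector of Sub-Saharan Africa — as a simulator and
Bayesian inference package for vector-control analysis.

Seasonal *A. gambiae* abundance in the Sahel is driven by rainfall, which
creates and expands larval breeding sites, and is regulated by
density-dependent competition among larvae in those sites. Understanding
that regulation matters operationally: interventions that kill adults
(insecticide-treated nets, indoor residual spraying) also reduce egg
input into breeding sites, while interventions that kill larvae or block
pupal emergence (larvicides such as BTI, pupacides such as pyriproxyfen)
interact with the density dependence itself. Models that treat adult
emergence as constant get these effects wrong.

## The model

Four compartments — early instars $E$, late instars $L$, pupae $P$,
adult females $M$ — with exponential stage durations:

$$
\dot E = \beta M - E/d_E - \mu_E(E,L)E,\quad
\dot L = E/d_E - L/d_L - \mu_L(E,L)L,
$$
$$
\dot P = L/d_L - P/d_P - \mu_P P,\quad
\dot M = \tfrac12 P/d_P - \mu_M M,
$$

with larval mortality linear in crowding,
$\mu_E = \mu_E^0(1 + (E+L)/K(t))$ and
$\mu_L = \mu_L^0(1 + \gamma(E+L)/K(t))$, where the carrying capacity
$K(t)$ is proportional to weighted recent rainfall (uniform, linear or
exponential memory kernel) with a dry-season floor set by a 20%
detectability argument. The basic reproduction number is

$$
R_0 = \tfrac12\,\frac{\beta}{\mu_M}\prod_{s\in\{E,L,P\}}\frac{1}{1+\mu_s d_s},
$$

and its density-dependent counterpart $R_{\mathrm{eff}}(t)$ equals 1
exactly at equilibrium. Fitting uses a negative binomial likelihood for
nightly catch counts over an adaptive random-walk Metropolis MCMC.
See the vignette (`vignettes/mosquito-population-dynamics.Rmd`) for the
full account.

## Worked example

```r
library(gambiaedyn)

p <- lifecycle_params()      # Sahelian field estimates
reproduction_numbers(p)
#> $R0               68.7     expected female offspring per female,
#>                            no density dependence (theoretical cap)
#> $lifetime_eggs    221      beta / mu_M
#> $aquatic_survival 0.622    P(egg survives to emergence), low density
#> $beta_max         26.9     oviposition upper bound, eggs/day

# a synthetic Sahelian village: one rainy season, overdispersed catches
sc  <- synthetic_scenario(lam = 15, seed = 42)
rf  <- generate_rainfall(sc)
kf  <- dry_season_floor(p, dispersion_r = 1)    # 0.687
cfg <- cc_config("exponential", tau = 4, lam = 15, K_floor = kf)
kser <- carrying_capacity_series(rf, cfg)
sim <- simulate_lifecycle(p, kser, lifecycle_equilibrium(p, kser[1, "K"]),
                          t_span = c(0, 364))
max(sim$states$M)                     # 28.0  adults at the seasonal peak (day 225)
max(reff_series(sim)$Reff)            # 43.9  Reff spike at the onset of the rains

# intervention league table at constant K
intervention_league_table(p, list(
  llin80       = list(llin = 0.8),
  irs80        = list(irs = 0.8),
  bti50        = list(larvicide_coverage = 0.5),
  llin80_bti50 = list(llin = 0.8, larvicide_coverage = 0.5)), K = 1e4)
#>      scenario adult_density percent_reduction
#>  llin80_bti50         332.3              90.9
#>         irs80         798.7              78.1
#>        llin80         800.5              78.0
#>         bti50        1756.2              51.8
```

The league table reads: at 50% breeding-site coverage, larviciding alone
halves adult density; 80% net coverage cuts it by ~78%; and combining
nets with larvicide — tools hitting different lifecycle stages — reaches
~91%, more than either alone.

Fitting synthetic (or real) catch data:

```r
fx <- fixture_village_set(seed = 1, n_villages = 2)
chain <- run_mcmc(fx$catches, fx$rainfall, n_iter = 5000, burn = 1000,
                  seed = 1)         # samples beta, gamma, tau, lam_i, r
posterior_summary(chain)
credible_envelope(chain, "v1")
```

A command-line interface wrapping the same functions is installed at
`exec/gambiaedyn` (subcommands `synth`, `simulate`, `r0`, `fit`,
`intervene`); run it without arguments for usage.

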