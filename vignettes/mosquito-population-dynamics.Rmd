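---
title: "Modelling Anopheles gambiae population dynamics with gambiaedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Anopheles gambiae population dynamics with gambiaedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gambiaedyn)
```

## The model

`gambiaedyn` simulates an *Anopheles gambiae* s.l. population through its
full lifecycle with four compartments: early larval instars $E$ (eggs plus
instars 1–2), late instars $L$ (instars 3–4), pupae $P$, and adult females
$M$:

$$
\begin{aligned}
\frac{dE}{dt} &= \beta M - \frac{E}{d_E} - \mu_E(E, L)\,E, &
\frac{dL}{dt} &= \frac{E}{d_E} - \frac{L}{d_L} - \mu_L(E, L)\,L,\\
\frac{dP}{dt} &= \frac{L}{d_L} - \frac{P}{d_P} - \mu_P P, &
\frac{dM}{dt} &= \frac{1}{2}\frac{P}{d_P} - \mu_M M.
\end{aligned}
$$

Each stage is left at rate $1/d$ (the reciprocal of its mean duration), so
individual stage durations are exponential; chaining three aquatic
compartments gives an approximately gamma-shaped egg-to-emergence time,
avoiding the biologically impossible near-zero development times a single
compartment would allow. Half of emerging adults are assumed female, males
are ignored beyond mating, adults do not senesce, and the gonotrophic cycle
is concordant (one blood meal per egg batch).

Larvae — but not pupae, which do not feed — compete for food. Competition
raises per-capita mortality *linearly* in total larval density relative to
the environmental carrying capacity $K(t)$:

$$
\mu_E(E, L) = \mu_E^0\left(1 + \frac{E+L}{K(t)}\right), \qquad
\mu_L(E, L) = \mu_L^0\left(1 + \gamma\,\frac{E+L}{K(t)}\right).
$$

The linear form is the parsimonious description of staggered-age-cohort
larval survival experiments and matches the "mortality proportional to
larval biomass" assumption of more detailed simulators; $\gamma$ lets
crowding fall more heavily on late instars (cannibalism of early instars
by late ones acts the other way, but the fitted $\gamma \approx 13$ says
competition dominates). This is contest-style competition: survivor numbers
saturate rather than crash as egg input grows.

### Parameters

Defaults in `lifecycle_params()` are posterior-median field estimates for
Sahelian *A. gambiae* (Garki District, Nigeria; water temperature
$\approx 28$°C):

| parameter | meaning | unit | default |
|---|---|---|---|
| `beta` | eggs laid per female per day | d$^{-1}$ | 21.19 |
| `d_E`, `d_L`, `d_P` | mean stage durations | days | 6.64, 3.72, 0.64 |
| `mu_E0`, `mu_L0` | low-density instar mortality | d$^{-1}$ | 0.034, 0.035 |
| `mu_P`, `mu_M` | pupal / adult mortality | d$^{-1}$ | 0.25, 0.096 |
| `gamma` | relative density dependence on $L$ | – | 13.25 |
| `eps_max`, `delta` | eggs per oviposition; cycle length | –, days | 93.6, 3 |
| `female_fraction` | female share of emergence | – | 0.5 |

`beta` is bounded above by the oviposition calculus
$\beta_{max} = \varepsilon_{max}\mu_M / (e^{\delta\mu_M}-1)$ (about 26.9
eggs/day at the defaults); the constructor warns if a supplied `beta`
exceeds it.

## Rainfall and carrying capacity

$K(t)$ is proportional to weighted recent rainfall, with three kernels
(`cc_config()`): the mean over the past $\tau$ days, a linearly weighted
mean (recent days count most), and an exponential kernel with mean
$2\tau$. Conventions:

* weights sit on integer day lags $0, 1, \dots$ (lag 0 = today) and sum
  to one, so constant rainfall $R$ maps to $K = \lambda R$ under every
  model;
* the uniform and linear kernels span lags $0..\lceil\tau\rceil - 1$ with
  a fractional final weight, making $K$ continuous in $\tau$ — needed
  because $\tau$ is a fitted parameter;
* the infinite-memory exponential kernel is truncated where its
  cumulative weight reaches 0.999 ($\approx 13.8\tau$ days) and
  renormalised;
* during the first few days of a record the kernel is renormalised over
  the available days.

All kernels predict $K \to 0$ in a long dry spell, which would
extinguish the population; real Sahelian populations persist and rebound
with the rains. When no mosquitoes are caught we assume one *could* have
been caught with probability 0.2, and `dry_season_floor()` computes the
$K$ whose equilibrium adult density makes a nightly negative binomial
catch non-zero exactly that often. The detection condition inverts in
closed form (mean $= r[(1-p)^{-1/r} - 1]$) and, because the equilibrium
is exactly linear in $K$, the floor follows from one equilibrium solve
(a residual check guards the linearity). The floor is applied as
$K(t) = \max(\lambda \cdot \text{weighted rain}, K_{floor})$ — a
substitute dry-season level, not a year-round additive baseline: the
wording "set to a level capable of supporting a small population" reads
as a floor on the environment ($K$), not on the mosquitoes ($M$), and a
$K$-level floor keeps the state dynamics self-consistent.

## Reproduction numbers

$R_0$ — female offspring per female absent density dependence — is the
female share of lifetime egg output times the product of aquatic
stage-survival probabilities:

$$
R_0 = \frac{1}{2}\,\frac{\beta}{\mu_M}
\prod_{s\in\{E,L,P\}} \frac{1}{1 + \mu_s d_s},
$$

where $1/(1+\mu d)$ is the probability that stage progression (rate
$1/d$) beats death (rate $\mu$) under the exponential-stage model.
Lifetime eggs are accounted as the continuous-mortality expectation
$\beta/\mu_M$ with $\beta$ the *fitted* daily rate in the ODEs — this is
the accounting consistent with the dynamical model, and the discrete
gonotrophic-survival sum is available through `oviposition_rate()`
(for per-cycle clutch $\varepsilon$, the geometric sum collapses to the
same closed form). At the default parameters $R_0 \approx 68.7$.
$R_{\text{eff}}$ (`effective_reproduction_number()`) replaces the
background larval mortalities with their density-dependent values; it
equals $R_0$ in an empty environment, decreases strictly with crowding,
and equals exactly 1 at the positive equilibrium. Fecundity and adult
mortality are held density independent throughout, so $\beta$ is not
damped at high larval density.

The constant-$K$ equilibrium itself (`lifecycle_equilibrium()`) is
reduced analytically to the scalar condition
$R_{\text{eff}}(x) = 1$ in $x = (E+L)/K$, whose left side is strictly
decreasing — a unique bracketed root, immune to the multiple-root
pathologies of solving the four coupled balance equations directly. The
remaining compartments follow by back-substitution, and the whole
equilibrium scales linearly in $K$.

## Interventions

**LLINs and IRS** act on adults through a per-encounter feeding-cycle
model (`adult_intervention_params()`): on each feeding attempt the
mosquito may be killed, repelled (and forced to retry, lengthening the
gonotrophic cycle by `gonotrophic_extension` days per failed attempt),
or feed. Coverage-weighted outcome probabilities combine nets
(pre-feed) and sprayed walls (post-feed resting). The transform returns
a modified parameter set: higher $\mu_M'$, longer $\delta'$, and a
lower $\beta'$ recomputed from the implied eggs-per-cycle at the new
cycle length and mortality — so zero coverage is exactly the identity.
The quantitative per-encounter constants of deployed products live in
companion transmission models; the defaults here are generic pyrethroid
values chosen only to reproduce the expected qualitative ordering
(high-coverage IRS the most lethal adult intervention), and no printed
efficacy figure is claimed for them.

**Larvicide (BTI)** multiplies the background aquatic death rates in
treated sites by $\upsilon$ (default 55.2, mimicking an 88% reduction
in observable larvae, equivalently ~99% fewer emerging adults per egg —
the unambiguous calibration, since "observable larvae" could mean $E$
or $E+L$). **Pupacide (PPF)** lets treated-site larvae develop and
compete normally but blocks a fraction $F_{PPF}$ (default 0.95) of
their emergence, exploiting the density-dependent mortality those
doomed larvae still impose on competitors. Both use a two-class model
(`simulate_larvicide()`, `simulate_pupacide()`): oviposition splits
$c : (1-c)$ between treated and untreated sites and each class sees its
share ($cK$, $(1-c)K$) of the carrying capacity, preserving the
"larvae distributed evenly across viable sites" assumption — at a
neutral treatment both classes then have identical per-site density, so
$c = 0$ and $\upsilon = 1$ (or $F_{PPF} = 0$) reduce exactly to the
base model. Ovipositing females are assumed not to avoid treated sites.
Insecticide decay is out of scope: everything refers to impact after
deployment, before waning.

`simulate_constant_emergence()` provides the adult-only comparator
(fixed emergence rate, no oviposition feedback) used to show that
ignoring the larval feedback underestimates intervention impact.

## Inference

The model is fitted to village-level nightly catches with a negative
binomial likelihood: predicted adult density $M(t, i)$ (village $i$
driven by its own rainfall, scaling factor $\lambda_i$) is the mean,
with dispersion $r$ shared across villages. $\lambda_i$ absorbs
habitat scale *and* catching effort, so no separate per-house offset
exists. The dry-season floor is recomputed at every proposal from the
proposed parameters and $r$, keeping the observation and process models
consistent. A failed ODE integration at a proposal returns $-\infty$
(rejection).

**Priors.** Published prior intervals for all Table-style parameters are
symmetric about their medians on the natural scale (e.g. the
oviposition-rate prior 12.75 with interval (0.64, 24.86)), so each is a
normal matched to its 95% bounds, truncated to positive support in the
sampler. A log-normal — the other natural choice for positive rates —
cannot reproduce these intervals: bound-matching one to the
oviposition-rate interval would put its median near 4 instead of 12.75.
The truncation removes at most ~2% of mass (for that widest prior) and
is immaterial elsewhere. The observation layer gets weak priors:
$r$ log-normal with median 1, $\lambda_i$ log-uniform over
$(10^{-4}, 10^6)$.

**Sampler.** `run_mcmc()` is an adaptive random-walk Metropolis on
log-transformed parameters (with the Jacobian included). During burn-in
a global scale adapts toward 23.4% acceptance by Robbins–Monro while
per-component proposal widths track the running posterior standard
deviations; both freeze at the end of burn-in so the retained chain
satisfies detailed balance. Chains are exactly reproducible given a
seed. Any subset of parameters can be sampled (`fit_params`), the rest
being fixed at prior medians or user values — the desk-scale default
samples $(\beta, \gamma, \tau, \lambda_i, r)$, the parameters the data
actually inform in one season.

**Outputs.** `posterior_summary()` gives equal-tailed 2.5/50/97.5%
quantiles; `credible_envelope()` simulates repeated joint-posterior
draws and returns pointwise inter-quartile and 95% trajectory bands;
`model_compare()` ranks rainfall models by DIC
($\overline{D} + \tfrac{1}{2}\mathrm{var}(D)$) plus an aggregate
posterior-predictive log score. The original analysis used a
supplementary "predicted posterior probability" whose recipe is not
public; DIC is the standard substitute for ranking likelihood-fitted
chains and is validated here only on synthetic model-recovery
experiments.

## Synthetic data

`synthetic_scenario()` and friends generate the study inputs the
package is tested against, emulating a single-rainy-season Sahelian
setting: a seasonal window (default onset day 150, 120 days) in which
days are wet with probability 0.8 and wet-day amounts are gamma
distributed with mean 6 mm — about 580 mm/year, a typical Sahel total;
villages share seasonality but differ in $\lambda_i$ (defaults spread
log-evenly over 5–40) and in their independently drawn rainfall;
catches are negative binomial draws around the hidden true dynamics
with $r = 1$, a strongly overdispersed observation process. What the
generator deliberately does *not* reproduce: multi-modal or multi-season
rainfall, rainfall flushing of larvae at extreme totals, temperature
effects, between-village parameter heterogeneity beyond $\lambda_i$, and
spatial structure among breeding sites. Passing the recovery tests
therefore demonstrates internal consistency of simulator + sampler under
the model's own assumptions, not fidelity to any real district's data.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable, adaptive) with a
  compiled right-hand side; default `rtol` $10^{-8}$, `atol` $10^{-10}$
  (likelihood evaluations use $10^{-6}/10^{-8}$ for speed). $K(t)$ is a
  daily step-function forcing (`fcontrol method = "constant"`): rainfall
  is daily and $K$ can jump orders of magnitude at season onset, so
  smooth interpolation would misrepresent it.
* Density dependence divides by $K$; tiny negative excursions are
  clipped to zero after integration, with a warning if they exceed 100
  `atol`.
* Degenerate inputs: $K \le 0$ is an explicit error everywhere (the
  floor must be applied upstream); a zero-share treated class with empty
  compartments contributes zero density rather than 0/0.
* Ties/edge cases: subcritical parameter sets ($R_0 \le 1$) return the
  extinction equilibrium; a fully lethal adult intervention (no feeding
  outcome possible) is an explicit error.

### Problem sizes

Chain lengths are configurable; the package's desk-scale defaults used
in its own validation are: recovery experiments with 2 villages × 1 year
of weekly catches, chains of 2,000 retained iterations after 600
burn-in, repeated over 10 seeds; rainfall-model recovery with 1 village
sampled every 4 days, 500-iteration chains per candidate model, 10
replicates; equilibrium-versus-integration checks over 20 prior draws.
Production fits should use the `n_iter = 50000` default (or more) with
a burn-in of at least 1,000.

## Known limitations

Single well-mixed habitat (real districts have heterogeneous discrete
breeding sites, which intensify regulation); egg-batch clumping ignored,
so predictions at near-elimination densities are unreliable; no
temperature dependence (rates are for ~28°C water); no adult
senescence or gonotrophic discordance; no interspecific competition
(*A. arabiensis*); no insecticide waning; larvicide and pupacide cannot
be combined in a single run (a third site class would be needed); and
the malaria transmission consequences of vector suppression are out of
scope entirely.
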