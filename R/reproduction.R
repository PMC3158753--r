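#' Maximum daily oviposition rate
#'
#' A female that survives to oviposit every `delta` days under constant
#' daily mortality `mu_M` lays, over her lifetime, an expected
#' \eqn{\varepsilon_{max} \sum_{k \ge 1} e^{-k \delta \mu_M}} eggs; divided
#' by the expected lifetime \eqn{1/\mu_M} this gives the population-level
#' daily oviposition rate
#' \deqn{\beta_{max} = \frac{\varepsilon_{max}\,\mu_M}{e^{\delta \mu_M} - 1}.}
#' In practice the realised `beta` is below this bound, as some eggs are
#' laid in unsuitable sites or fail to hatch.
#'
#' @param eps_max Maximum eggs per oviposition.
#' @param delta Gonotrophic cycle length (days).
#' @param mu_M Adult daily mortality (1/day).
#' @return Eggs per female per day.
#' @examples
#' oviposition_rate(93.6, 3, 0.096)  # ~26.9 eggs/day
#' @export
oviposition_rate <- function(eps_max, delta, mu_M) {
  stopifnot(eps_max > 0, delta > 0, mu_M > 0)
  eps_max * mu_M / (expm1(delta * mu_M))
}

#' Probability that an egg survives to adult emergence
#'
#' Under the exponential-stage formulation, survival through a stage with
#' mean duration `d` and death rate `mu` is the probability that
#' progression (rate `1/d`) beats death: `(1/d) / (1/d + mu) = 1/(1 + mu d)`.
#' The egg-to-imago survival is the product over the three aquatic stages.
#'
#' @param params A [lifecycle_params()] object (supplies durations and
#'   `mu_P`).
#' @param mu_E,mu_L Early/late-instar mortality rates to use; default the
#'   low-density background rates. Pass the output of
#'   [density_dependent_rates()] for crowded conditions.
#' @return Survival fraction in (0, 1].
#' @export
egg_to_adult_survival <- function(params, mu_E = params$mu_E0,
                                  mu_L = params$mu_L0) {
  1 / ((1 + mu_E * params$d_E) * (1 + mu_L * params$d_L) *
         (1 + params$mu_P * params$d_P))
}

#' Basic reproduction number of the mosquito population
#'
#' Expected number of adult female offspring produced per adult female
#' over her lifetime in the absence of density-dependent larval
#' mortality:
#' \deqn{R_0 = \tfrac{1}{2} \frac{\beta}{\mu_M}
#'   \prod_{s \in \{E,L,P\}} \frac{1}{1 + \mu_s d_s},}
#' i.e. female fraction times lifetime egg output times egg-to-imago
#' survival at background rates. This is a theoretical upper bound: in
#' any real population density dependence lowers the realised
#' reproduction number.
#'
#' @param params A [lifecycle_params()] object.
#' @return `R0` (dimensionless).
#' @examples
#' basic_reproduction_number(lifecycle_params())  # about 67
#' @export
basic_reproduction_number <- function(params) {
  params$female_fraction * (params$beta / params$mu_M) *
    egg_to_adult_survival(params)
}

#' Effective reproduction number at given larval densities
#'
#' Same accounting as [basic_reproduction_number()] but conditioning on
#' the density-dependent larval mortality rates at the current early- and
#' late-instar densities. Per-female fecundity and adult mortality are
#' density independent, so `Reff` differs from `R0` only through the
#' aquatic survival term; it decreases with increasing larval density and
#' equals 1 exactly at the stable positive equilibrium, where each female
#' just replaces herself.
#'
#' @param params A [lifecycle_params()] object.
#' @param E,L Early/late-instar densities.
#' @param K Carrying capacity (> 0).
#' @return `Reff` (dimensionless), `<= R0`.
#' @examples
#' p <- lifecycle_params()
#' effective_reproduction_number(p, E = 0, L = 0, K = 1000)  # = R0
#' @export
effective_reproduction_number <- function(params, E, L, K) {
  dd <- density_dependent_rates(E, L, K, params)
  params$female_fraction * (params$beta / params$mu_M) *
    egg_to_adult_survival(params, dd$mu_E, dd$mu_L)
}

#' Effective reproduction number along a simulated trajectory
#'
#' Applies [effective_reproduction_number()] pointwise to a simulation.
#' In seasonal runs the series peaks at the onset of the rains, when the
#' carrying capacity expands while breeding sites are still nearly empty,
#' and relaxes back towards 1 as larval competition builds up.
#'
#' @param sim A `mosq_sim` object from [simulate_lifecycle()].
#' @param params A [lifecycle_params()] object; defaults to the parameters
#'   stored in `sim`.
#' @return Data frame with columns `time` and `Reff`.
#' @export
reff_series <- function(sim, params = sim$params) {
  stopifnot(inherits(sim, "mosq_sim"))
  reff <- effective_reproduction_number(params, sim$states$E, sim$states$L,
                                        sim$K_values)
  data.frame(time = sim$times, Reff = reff)
}

#' Reproduction-number summary
#'
#' Convenience wrapper returning the basic reproduction number together
#' with its component factors.
#'
#' @param params A [lifecycle_params()] object.
#' @return Named list: `R0`, `lifetime_eggs` (`beta/mu_M`),
#'   `aquatic_survival`, `beta_max` (oviposition upper bound).
#' @export
reproduction_numbers <- function(params) {
  list(R0 = basic_reproduction_number(params),
       lifetime_eggs = params$beta / params$mu_M,
       aquatic_survival = egg_to_adult_survival(params),
       beta_max = oviposition_rate(params$eps_max, params$delta,
                                   params$mu_M))
}
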