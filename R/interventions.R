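#' Adult-stage intervention parameters (LLINs and IRS)
#'
#' Per-encounter description of long-lasting insecticide-treated nets and
#' indoor residual spraying acting on an indoor, night-biting vector.
#' On each feeding attempt a mosquito protected by a net is killed with
#' probability `llin_kill`, repelled (and forced to try again) with
#' probability `llin_repel`, and otherwise proceeds; a mosquito entering
#' a sprayed house is repelled with probability `irs_repel` or feeds and
#' is killed while resting on the wall with probability `irs_kill`. Each
#' repeated attempt adds `gonotrophic_extension` days to the gonotrophic
#' cycle. The default per-encounter probabilities are generic pyrethroid
#' values chosen to give the expected qualitative ordering (IRS at high
#' coverage more lethal than LLINs); they should be replaced with
#' locally calibrated values for quantitative work.
#'
#' @param llin_coverage Proportion of people sleeping under nets, in
#'   `[0, 1]`.
#' @param irs_coverage Proportion of houses sprayed, in `[0, 1]`.
#' @param llin_kill,llin_repel Per-encounter kill/repel probabilities for
#'   nets (`kill + repel <= 1`; the remainder is a successful feed).
#' @param irs_kill,irs_repel Per-encounter kill/repel probabilities for
#'   spraying.
#' @param gonotrophic_extension Days added to the cycle per failed
#'   attempt.
#' @return An `adult_intervention_params` object.
#' @export
adult_intervention_params <- function(llin_coverage = 0, irs_coverage = 0,
                                      llin_kill = 0.41, llin_repel = 0.56,
                                      irs_kill = 0.60, irs_repel = 0.20,
                                      gonotrophic_extension = 0.5) {
  iv <- list(llin_coverage = llin_coverage, irs_coverage = irs_coverage,
             llin_kill = llin_kill, llin_repel = llin_repel,
             irs_kill = irs_kill, irs_repel = irs_repel,
             gonotrophic_extension = gonotrophic_extension)
  probs <- unlist(iv[-7])
  if (any(probs < 0 | probs > 1))
    stop("coverages and per-encounter probabilities must lie in [0, 1]")
  if (llin_kill + llin_repel > 1 || irs_kill + irs_repel > 1)
    stop("kill + repel must not exceed 1 for either tool")
  if (gonotrophic_extension < 0) stop("gonotrophic_extension must be >= 0")
  structure(iv, class = "adult_intervention_params")
}

#' Effects of LLINs and IRS on adult lifecycle parameters
#'
#' Folds the per-encounter feeding-cycle model of
#' [adult_intervention_params()] into modified adult parameters. Per
#' feeding attempt the mosquito dies with probability
#' `d = c_N k_N + q c_S k_S`, repeats with `w = c_N r_N + q c_S r_S`
#' (where `q = 1 - c_N (k_N + r_N)` is the probability of getting past
#' the net) and feeds successfully otherwise. Repeats lengthen the
#' gonotrophic cycle (`delta' = delta + extension * w / (1 - w)`);
#' intervention mortality adds a per-cycle hazard
#' (`mu_M' = mu_M - log(s / (s + d)) / delta'`); and the daily
#' oviposition rate is recomputed from the implied eggs-per-cycle at the
#' new cycle length and mortality, so `beta' < beta` whenever feeding is
#' delayed or lethal. With all coverages zero the input is returned
#' unchanged.
#'
#' @param base A [lifecycle_params()] object.
#' @param iv An [adult_intervention_params()] object.
#' @return A modified [lifecycle_params()] object (`beta`, `delta`,
#'   `mu_M` updated).
#' @examples
#' p <- lifecycle_params()
#' adult_intervention_effects(p, adult_intervention_params(llin_coverage = 0.8))
#' @export
adult_intervention_effects <- function(base, iv) {
  stopifnot(inherits(iv, "adult_intervention_params"))
  cN <- iv$llin_coverage; cS <- iv$irs_coverage
  q <- 1 - cN * (iv$llin_kill + iv$llin_repel)
  d <- cN * iv$llin_kill + q * cS * iv$irs_kill
  w <- cN * iv$llin_repel + q * cS * iv$irs_repel
  s <- 1 - d - w
  if (s + d <= 0)
    stop("interventions leave no absorbing outcome: feeding cycle never ends")
  ps <- s / (s + d)                       # P(eventually feeds | one cycle)
  if (ps <= 0)
    stop("interventions are fully lethal before any feed; adult dynamics degenerate")
  delta2 <- base$delta + iv$gonotrophic_extension * w / (1 - w)
  mu2 <- base$mu_M - log(ps) / delta2
  eps_eff <- base$beta * expm1(base$delta * base$mu_M) / base$mu_M
  beta2 <- eps_eff * mu2 / expm1(delta2 * mu2)
  out <- base
  out$beta <- beta2
  out$delta <- delta2
  out$mu_M <- mu2
  out
}

#' Larvicide parameters
#'
#' A larvicide (e.g. *Bacillus thuringiensis israelensis*, BTI) applied
#' to a fraction `coverage` of breeding sites multiplies the background
#' aquatic death rates (`mu_E0`, `mu_L0`, `mu_P`) in treated sites by
#' `upsilon`. The default `upsilon = 55.2` mimics an 88% reduction in
#' observable larvae, corresponding to a ~99% reduction in adult
#' emergence per egg.
#'
#' @param upsilon Mortality multiplication factor (>= 1).
#' @param coverage Proportion of breeding sites treated, in `[0, 1]`.
#' @return A `larvicide_params` object.
#' @export
larvicide_params <- function(upsilon = 55.2, coverage = 0) {
  if (upsilon < 1) stop("upsilon must be >= 1")
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  structure(list(upsilon = upsilon, coverage = coverage),
            class = "larvicide_params")
}

#' Pupacide parameters
#'
#' A pupacide (e.g. the juvenile hormone analogue pyriproxyfen, PPF)
#' applied to a fraction `coverage` of breeding sites prevents a fraction
#' `F_PPF` of pupae in treated sites from emerging as adults. Treated
#' larvae still develop and compete, so the doomed pupae continue to
#' contribute to density-dependent regulation.
#'
#' @param F_PPF Efficacy: fraction of treated-site emergence prevented,
#'   in `[0, 1]`. Default 0.95.
#' @param coverage Proportion of breeding sites treated, in `[0, 1]`.
#' @return A `pupacide_params` object.
#' @export
pupacide_params <- function(F_PPF = 0.95, coverage = 0) {
  if (F_PPF < 0 || F_PPF > 1) stop("F_PPF must lie in [0, 1]")
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  structure(list(F_PPF = F_PPF, coverage = coverage),
            class = "pupacide_params")
}

# split a base initial state into treated/untreated compartments
# (larvae assumed evenly distributed across sites)
split_init <- function(init, cov) {
  if (length(init) == 7) return(as.numeric(init))
  s <- state_vec(init)
  c(E = (1 - cov) * s[["E"]], L = (1 - cov) * s[["L"]],
    P = (1 - cov) * s[["P"]],
    E_T = cov * s[["E"]], L_T = cov * s[["L"]], P_T = cov * s[["P"]],
    M = s[["M"]])
}

simulate_treated <- function(func, params, xtra, cov, K_of_t, init, t_span,
                             dt_out, rtol, atol) {
  forc <- k_forcing(K_of_t, t_span)
  times <- seq(t_span[1], t_span[2], by = dt_out)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  y0 <- split_init(init, cov)
  m <- integrate_compiled(func, y0, c_parms(params, xtra = xtra, cov = cov),
                          forc, times, rtol, atol)
  colnames(m) <- c("E", "L", "P", "E_T", "L_T", "P_T", "M")
  kidx <- findInterval(times, forc[, 1], all.inside = TRUE)
  structure(list(times = times,
                 states = as.data.frame(m),
                 K_values = forc[kidx, 2],
                 params = params),
            class = c("mosq_sim_treated", "mosq_sim"))
}

#' Simulate the lifecycle under larviciding
#'
#' Two-compartment extension of [simulate_lifecycle()]: a fraction
#' `lv$coverage` of breeding sites is treated, oviposition splits
#' `coverage : (1 - coverage)` between treated and untreated sites
#' (larvae distributed evenly across viable sites), each compartment sees
#' its share of the carrying capacity, and treated-site background
#' aquatic mortalities are multiplied by `lv$upsilon`. With zero coverage
#' or `upsilon = 1` the adult dynamics reduce exactly to the base model.
#'
#' @param params A [lifecycle_params()] object.
#' @param lv A [larvicide_params()] object.
#' @inheritParams simulate_lifecycle
#' @param init Either a base [lifecycle_state()] (aquatic stages are
#'   split across treated/untreated sites by coverage) or a 7-vector
#'   `(E, L, P, E_T, L_T, P_T, M)`.
#' @return A `mosq_sim_treated` object; `states` has columns
#'   `E, L, P, E_T, L_T, P_T, M`.
#' @export
simulate_larvicide <- function(params, lv, K_of_t,
                               init = lifecycle_state(M = 1),
                               t_span = c(0, 365), dt_out = 1,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(lv, "larvicide_params"))
  simulate_treated("mosq_bti", params, lv$upsilon, lv$coverage,
                   K_of_t, init, t_span, dt_out, rtol, atol)
}

#' Simulate the lifecycle under pupaciding
#'
#' As [simulate_larvicide()], but treated-site larvae develop and compete
#' under the normal density-dependent rates while only a fraction
#' `1 - pv$F_PPF` of their emerging pupae joins the adult pool. This
#' exploits density-dependent regulation: larvae destined to be killed at
#' emergence still suppress their competitors. `F_PPF = 0` reduces to the
#' base model.
#'
#' @param params A [lifecycle_params()] object.
#' @param pv A [pupacide_params()] object.
#' @inheritParams simulate_larvicide
#' @return A `mosq_sim_treated` object.
#' @export
simulate_pupacide <- function(params, pv, K_of_t,
                              init = lifecycle_state(M = 1),
                              t_span = c(0, 365), dt_out = 1,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(pv, "pupacide_params"))
  simulate_treated("mosq_ppf", params, pv$F_PPF, pv$coverage,
                   K_of_t, init, t_span, dt_out, rtol, atol)
}

#' Constant-emergence comparator model
#'
#' The adult-only model used by many vector-control analyses: adults
#' emerge at a fixed rate regardless of what happens in breeding sites,
#' `dM/dt = emergence_rate - mu_M * M`, with closed-form equilibrium
#' `M* = emergence_rate / mu_M`. Because it lacks the oviposition
#' feedback (fewer adults lay fewer eggs), it underestimates the
#' impact of adult-killing interventions relative to the full lifecycle
#' model. `emergence_rate` is typically set to the pre-intervention
#' recruitment `female_fraction * P* / d_P`.
#'
#' @param params A [lifecycle_params()] object (supplies `mu_M`; possibly
#'   modified by [adult_intervention_effects()]).
#' @param emergence_rate Adult female emergence rate (per day, >= 0).
#' @param init_M Initial adult density; defaults to the model's own
#'   equilibrium.
#' @param t_span,dt_out Output grid.
#' @return A `mosq_sim` object whose `states` has column `M` only.
#' @export
simulate_constant_emergence <- function(params, emergence_rate,
                                        init_M = emergence_rate / params$mu_M,
                                        t_span = c(0, 365), dt_out = 1) {
  stopifnot(emergence_rate >= 0, init_M >= 0)
  times <- seq(t_span[1], t_span[2], by = dt_out)
  Mstar <- emergence_rate / params$mu_M
  M <- Mstar + (init_M - Mstar) * exp(-params$mu_M * (times - times[1]))
  structure(list(times = times, states = data.frame(M = M),
                 K_values = rep(NA_real_, length(times)), params = params),
            class = "mosq_sim")
}

#' Percent reduction in adult density between two runs
#'
#' Headline comparison for intervention scenarios:
#' `100 * (1 - M_scenario / M_baseline)`, evaluated either at the final
#' state (post-transient equilibrium) or as a mean over a trailing
#' window (seasonal average).
#'
#' @param baseline,scenario Simulation objects (any class with
#'   `times`/`states$M`), on matched time grids.
#' @param type `"final"` (default) or `"mean"`.
#' @param window Trailing window length in days for `type = "mean"`.
#' @return Percentage reduction (positive when the scenario suppresses
#'   mosquitoes).
#' @export
percent_reduction <- function(baseline, scenario,
                              type = c("final", "mean"), window = 90) {
  type <- match.arg(type)
  if (!isTRUE(all.equal(baseline$times, scenario$times)))
    stop("baseline and scenario must share a time grid")
  summar <- function(sim) {
    M <- sim$states$M
    if (type == "final") return(M[length(M)])
    keep <- sim$times >= max(sim$times) - window
    mean(M[keep])
  }
  Mb <- summar(baseline)
  if (Mb <= 0) stop("baseline adult density is zero: reduction undefined")
  100 * (1 - summar(scenario) / Mb)
}
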