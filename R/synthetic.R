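#' Synthetic study scenario
#'
#' Configuration for generating Sahelian-style synthetic inputs: a
#' single-rainy-season rainfall profile, hidden "true" mosquito dynamics
#' under the lifecycle model, and overdispersed nightly catches. The
#' defaults emulate the kind of setting the model is meant for — one
#' rainy season of about four months, roughly 550-600 mm of annual rain,
#' villages differing only in a habitat/catchability scaling factor, no
#' mosquitoes detectable through most of the dry season.
#'
#' @param params True [lifecycle_params()].
#' @param lam Village scaling factors (one per village).
#' @param r True negative binomial dispersion of nightly catches.
#' @param onset Day of year the rains begin.
#' @param duration Length of the rainy season (days).
#' @param intensity Mean rainfall on a wet day (mm).
#' @param wet_prob Probability a rainy-season day is wet.
#' @param shape Gamma shape of wet-day rainfall amounts.
#' @param model,tau Rainfall-to-K model and memory used for the truth.
#' @param detect_prob Dry-season detectability defining the K floor.
#' @param seed Base random seed; all generators are deterministic given
#'   the scenario seed.
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(params = lifecycle_params(),
                               lam = c(10, 25), r = 1,
                               onset = 150, duration = 120,
                               intensity = 6, wet_prob = 0.8,
                               shape = 0.8,
                               model = "exponential", tau = 4,
                               detect_prob = 0.2, seed = 1) {
  stopifnot(all(lam >= 0), r > 0, duration > 0, intensity > 0,
            wet_prob > 0, wet_prob <= 1, shape > 0)
  structure(list(params = params, lam = lam, r = r, onset = onset,
                 duration = duration, intensity = intensity,
                 wet_prob = wet_prob, shape = shape, model = model,
                 tau = tau, detect_prob = detect_prob,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a synthetic daily rainfall series
#'
#' Windowed wet-day gamma model: days inside the seasonal window are wet
#' with probability `wet_prob` and wet-day amounts are gamma distributed
#' with mean `intensity`; all other days are dry. Deterministic given the
#' seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_years Number of years to generate.
#' @param start_date First calendar day of the series.
#' @param seed Seed; defaults to the scenario seed.
#' @return A [rainfall_series()].
#' @export
generate_rainfall <- function(scenario, n_years = 1,
                              start_date = as.Date("1971-01-01"),
                              seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(as.integer(seed))
  n <- 365L * n_years
  doy <- ((seq_len(n) - 1L) %% 365L) + 1L
  in_season <- doy >= scenario$onset &
    doy < scenario$onset + scenario$duration
  wet <- in_season & stats::runif(n) < scenario$wet_prob
  rain <- numeric(n)
  rain[wet] <- stats::rgamma(sum(wet), shape = scenario$shape,
                             scale = scenario$intensity / scenario$shape)
  rainfall_series(start_date + 0:(n - 1), rain)
}

# truth dynamics for one village under a scenario
true_dynamics <- function(scenario, rainfall, lam) {
  p <- scenario$params
  kf <- dry_season_floor(p, scenario$r, scenario$detect_prob)
  cfg <- cc_config(scenario$model, tau = scenario$tau, lam = lam,
                   K_floor = kf)
  kser <- carrying_capacity_series(rainfall, cfg)
  init <- lifecycle_equilibrium(p, kser[1, "K"])
  simulate_lifecycle(p, kser, init, t_span = c(0, nrow(rainfall) - 1),
                     dt_out = 1)
}

#' Generate synthetic nightly catch counts
#'
#' Runs the observation model generatively: simulates the true dynamics
#' for each village under its rainfall and scaling factor, then draws
#' nightly counts `N ~ NegBin(mean = M(t), dispersion = r)` on the
#' sampling days.
#'
#' @param scenario A [synthetic_scenario()].
#' @param rainfall A [rainfall_series()] (shared) or named list per
#'   village.
#' @param sampling_days Days since series start on which catches are
#'   made; default every 7th day.
#' @param villages Village names; default `v1, v2, ...` along
#'   `scenario$lam`.
#' @param seed Seed; defaults to the scenario seed.
#' @return A [catch_data()] frame.
#' @export
generate_catches <- function(scenario, rainfall, sampling_days = NULL,
                             villages = paste0("v", seq_along(scenario$lam)),
                             seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            length(villages) == length(scenario$lam))
  if (inherits(rainfall, "rainfall_series"))
    rainfall <- stats::setNames(rep(list(rainfall), length(villages)),
                                villages)
  set.seed(as.integer(seed))
  out <- NULL
  for (i in seq_along(villages)) {
    rs <- rainfall[[villages[i]]]
    days <- sampling_days
    if (is.null(days)) days <- seq(7, nrow(rs) - 1, by = 7)
    if (scenario$lam[i] > 0) {
      sim <- true_dynamics(scenario, rs, scenario$lam[i])
      mu <- sim$states$M[match(days, sim$times)]
      n <- stats::rnbinom(length(days), size = scenario$r,
                          mu = pmax(mu, 1e-12))
    } else {
      n <- rep(0L, length(days))
    }
    out <- rbind(out, data.frame(date = rs$date[1] + days,
                                 village = villages[i], count = n))
  }
  catch_data(out$date, out$village, out$count)
}

#' Synthetic multi-village fixture
#'
#' A ready-made study set emulating a Sahelian district survey: several
#' villages sharing the same seasonality but with distinct scaling
#' factors and independently drawn rainfall, plus the corresponding
#' nightly catches. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param n_villages Number of villages (default 8).
#' @param n_years Years of daily rainfall per village.
#' @param scenario Optionally a pre-built [synthetic_scenario()]; its
#'   `lam` must have length `n_villages`.
#' @return List with elements `scenario`, `rainfall` (named list of
#'   [rainfall_series()]), `catches` ([catch_data()]), and `truth`
#'   (named list of true per-village dynamics as `mosq_sim` objects).
#' @export
fixture_village_set <- function(seed = 1, n_villages = 8, n_years = 1,
                                scenario = NULL) {
  if (is.null(scenario)) {
    lam <- round(exp(seq(log(5), log(40), length.out = n_villages)), 1)
    scenario <- synthetic_scenario(lam = lam, seed = seed)
  }
  stopifnot(length(scenario$lam) == n_villages)
  villages <- paste0("v", seq_len(n_villages))
  rainfall <- stats::setNames(lapply(seq_len(n_villages), function(i)
    generate_rainfall(scenario, n_years = n_years,
                      seed = scenario$seed + 1000L * i)), villages)
  catches <- generate_catches(scenario, rainfall, villages = villages,
                              seed = scenario$seed)
  truth <- stats::setNames(lapply(seq_len(n_villages), function(i)
    true_dynamics(scenario, rainfall[[i]], scenario$lam[i])), villages)
  list(scenario = scenario, rainfall = rainfall, catches = catches,
       truth = truth)
}
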