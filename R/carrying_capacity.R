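#' Daily rainfall series
#'
#' Container for a contiguous daily rainfall record for one village.
#' Internally, model time is measured in days since the first record
#' (day 0 = first date).
#'
#' @param dates `Date` vector, contiguous daily, increasing.
#' @param rain_mm Non-negative daily rainfall (mm).
#' @return A `rainfall_series` data frame with columns `date`, `rain_mm`.
#' @export
rainfall_series <- function(dates, rain_mm) {
  dates <- as.Date(dates)
  if (length(dates) != length(rain_mm)) stop("dates and rain_mm lengths differ")
  if (length(dates) < 2) stop("rainfall series needs at least 2 days")
  dd <- as.integer(diff(dates))
  if (any(dd != 1L))
    stop("rainfall dates must be contiguous daily; gap after ",
         format(dates[which(dd != 1L)[1]]), " (no imputation is performed)")
  if (any(!is.finite(rain_mm)) || any(rain_mm < 0))
    stop("rain_mm must be finite and >= 0")
  structure(data.frame(date = dates, rain_mm = as.numeric(rain_mm)),
            class = c("rainfall_series", "data.frame"))
}

#' Carrying-capacity configuration
#'
#' How daily rainfall maps to the environmental carrying capacity
#' `K(t)`. Three weighting models are supported, all normalised so that
#' constant rainfall `R` gives `K = lam * R`:
#' \describe{
#'   \item{`mean`}{mean rainfall over the past `tau` days (uniform
#'     weights).}
#'   \item{`linear`}{linearly weighted mean over the past `tau` days,
#'     recent days weighted most.}
#'   \item{`exponential`}{past rainfall weighted by an exponential
#'     distribution with mean `2 * tau` days.}
#' }
#' During extended dry spells all three kernels predict `K = 0`, which
#' cannot sustain any population; `K` is therefore floored at `K_floor`,
#' a small dry-season carrying capacity (see [dry_season_floor()]).
#'
#' @param model One of `"exponential"`, `"mean"`, `"linear"`.
#' @param tau Rainfall memory (days, > 0); need not be an integer.
#' @param lam Village-specific scaling factor (> 0) from mm of weighted
#'   rainfall to carrying capacity (larvae).
#' @param K_floor Dry-season minimum carrying capacity (>= 0).
#' @return A `cc_config` object.
#' @export
cc_config <- function(model = c("exponential", "mean", "linear"),
                      tau = 4, lam = 1, K_floor = 0) {
  model <- match.arg(model)
  if (tau <= 0) stop("tau must be > 0")
  if (lam <= 0) stop("lam must be > 0")
  if (K_floor < 0) stop("K_floor must be >= 0")
  structure(list(model = model, tau = tau, lam = lam, K_floor = K_floor),
            class = "cc_config")
}

#' Rainfall weighting kernel
#'
#' Weights over integer day lags (lag 0 = today) for the three rainfall
#' models of [cc_config()]; normalised to sum to 1. The exponential
#' kernel (mean `2 * tau`) has infinite support and is truncated at the
#' lag where its cumulative weight reaches 0.999, then renormalised. The
#' uniform and linear kernels take fractional end weights so K varies
#' continuously in `tau` (useful when `tau` is being fitted).
#'
#' @param model `"mean"`, `"linear"` or `"exponential"`.
#' @param tau Memory length (days).
#' @return Numeric weight vector; element `i` is the weight of lag `i - 1`.
#' @export
rainfall_weights <- function(model, tau) {
  w <- switch(model,
    mean = {
      n <- ceiling(tau)
      pmin(1, tau - seq_len(n) + 1) / tau
    },
    linear = {
      n <- ceiling(tau)
      pmax(0, tau - seq_len(n) + 1)
    },
    exponential = {
      q <- exp(-1 / (2 * tau))          # daily decay, mean 2*tau
      n <- ceiling(log(0.001) / log(q)) # cumulative weight >= 0.999
      q^(seq_len(n) - 1)
    },
    stop("unknown rainfall model: ", model))
  w / sum(w)
}

#' Carrying capacity from rainfall
#'
#' Evaluates `K(t) = max(lam * weighted recent rainfall, K_floor)` for a
#' rainfall series under a [cc_config()]. For the first few days of the
#' record, where the kernel would reach before the series start, the
#' available weights are renormalised (so a constant-rainfall record
#' still maps to a constant `K`).
#'
#' @param rainfall A [rainfall_series()].
#' @param config A [cc_config()].
#' @param t Evaluation times: days since the series start (day 0 = first
#'   record) or `Date`s; `NULL` (default) evaluates the whole series.
#' @return Numeric vector of carrying capacities at `t`.
#' @examples
#' rs <- rainfall_series(as.Date("2000-01-01") + 0:9, rep(5, 10))
#' carrying_capacity(rs, cc_config("mean", tau = 4, lam = 10))
#' @export
carrying_capacity <- function(rainfall, config, t = NULL) {
  stopifnot(inherits(rainfall, "rainfall_series"), inherits(config, "cc_config"))
  w <- rainfall_weights(config$model, config$tau)
  r <- rainfall$rain_mm
  n <- length(r)
  wr <- as.numeric(stats::filter(r, w, method = "convolution", sides = 1))
  # renormalised partial kernels for the run-in days
  head_n <- min(length(w) - 1L, n)
  for (i in seq_len(head_n)) {
    wi <- w[seq_len(i)]
    wr[i] <- sum(wi * r[i:1]) / sum(wi)
  }
  K <- pmax(config$lam * wr, config$K_floor)
  if (is.null(t)) return(K)
  if (inherits(t, "Date")) t <- as.numeric(t - rainfall$date[1])
  if (any(t < 0)) stop("t before the start of the rainfall series")
  if (any(t > n - 1)) stop("t beyond the end of the rainfall series")
  K[floor(t) + 1]
}

#' Carrying-capacity series for simulation
#'
#' The whole-series counterpart of [carrying_capacity()], shaped as the
#' (time, K) table that [simulate_lifecycle()] and the intervention
#' simulators accept as a daily step-function forcing.
#'
#' @inheritParams carrying_capacity
#' @return Two-column matrix `time` (days since series start) and `K`.
#' @export
carrying_capacity_series <- function(rainfall, config) {
  K <- carrying_capacity(rainfall, config)
  cbind(time = seq_along(K) - 1, K = K)
}

#' Dry-season carrying-capacity floor
#'
#' During extended dry spells the rainfall models predict a zero carrying
#' capacity, yet the population must persist at low density for the rains
#' to restart it. When no mosquitoes are caught, a mosquito is assumed
#' catchable with probability `detect_prob` (default 0.2); the floor is
#' the carrying capacity whose equilibrium adult density `M*` makes a
#' nightly negative binomial catch (mean `catch_scale * M*`, dispersion
#' `r`) non-zero with exactly that probability. The detection condition
#' inverts in closed form,
#' \deqn{\mathrm{mean} = r\left[(1 - p)^{-1/r} - 1\right],}
#' and the `K` supporting the required `M*` is found by bracketed
#' root-finding on the equilibrium (which is linear in `K`).
#'
#' @param params A [lifecycle_params()] object; must have `R0 > 1` or no
#'   positive population can be supported at any `K`.
#' @param dispersion_r Negative binomial dispersion of nightly catches.
#' @param detect_prob Probability of catching at least one mosquito per
#'   night at the floor population; in (0, 1).
#' @param catch_scale Expected catch per unit adult density.
#' @return `K_floor` (> 0).
#' @examples
#' dry_season_floor(lifecycle_params(), dispersion_r = 1)
#' @export
dry_season_floor <- function(params, dispersion_r, detect_prob = 0.2,
                             catch_scale = 1) {
  if (detect_prob <= 0 || detect_prob >= 1)
    stop("detect_prob must lie strictly between 0 and 1")
  if (dispersion_r <= 0) stop("dispersion_r must be > 0")
  if (catch_scale <= 0) stop("catch_scale must be > 0")
  if (basic_reproduction_number(params) <= 1)
    stop("R0 <= 1: no carrying capacity can sustain a detectable population")
  mu_target <- dispersion_r * ((1 - detect_prob)^(-1 / dispersion_r) - 1)
  M_target <- mu_target / catch_scale
  # equilibrium M is exactly linear in K (density dependence enters only
  # through (E+L)/K), so inverting the slope at a reference K is exact;
  # a residual check guards the assumption
  K_ref <- 1e4
  slope <- lifecycle_equilibrium(params, K_ref)[["M"]] / K_ref
  K0 <- M_target / slope
  resid <- abs(lifecycle_equilibrium(params, K0)[["M"]] - M_target)
  if (resid > 1e-6 * M_target)
    K0 <- stats::uniroot(function(K)
      lifecycle_equilibrium(params, K)[["M"]] - M_target,
      c(K0 / 2, K0 * 2), extendInt = "yes",
      tol = .Machine$double.eps^0.5 * K0)$root
  K0
}
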