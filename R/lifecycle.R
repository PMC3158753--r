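#' Density-dependent larval mortality rates
#'
#' Intra-specific competition among larvae raises per-capita mortality
#' linearly with total larval density relative to the environmental
#' carrying capacity:
#' \deqn{\mu_E(E, L) = \mu_E^0 (1 + (E+L)/K), \qquad
#'       \mu_L(E, L) = \mu_L^0 (1 + \gamma (E+L)/K),}
#' where `gamma` allows density dependence to act more strongly on late
#' instars. Pupae do not feed and experience no density dependence.
#'
#' @param E,L Early- and late-instar densities (>= 0).
#' @param K Carrying capacity (> 0). A non-positive `K` is an error: during
#'   extended dry spells the dry-season floor must be applied upstream (see
#'   [dry_season_floor()]).
#' @param params A [lifecycle_params()] object.
#' @return Named list with components `mu_E` and `mu_L` (1/day).
#' @examples
#' p <- lifecycle_params()
#' density_dependent_rates(500, 500, K = 1000, params = p)
#' @export
density_dependent_rates <- function(E, L, K, params) {
  if (any(K <= 0))
    stop("K must be > 0: degenerate environment; apply the dry-season ",
         "carrying-capacity floor upstream")
  if (any(E < 0) || any(L < 0)) stop("E and L must be >= 0")
  x <- (E + L) / K
  list(mu_E = params$mu_E0 * (1 + x),
       mu_L = params$mu_L0 * (1 + params$gamma * x))
}

#' Time derivatives of the lifecycle model
#'
#' The lifecycle ODE system. Eggs hatch into early instars fed by
#' oviposition `beta * M`; stages progress at rates `1/d_E`, `1/d_L`,
#' `1/d_P`; larvae die at the density-dependent rates of
#' [density_dependent_rates()]; a fraction `female_fraction` of emerging
#' pupae joins the adult female pool, which dies at constant rate `mu_M`.
#'
#' @param state A [lifecycle_state()] (or named vector with E, L, P, M).
#' @param params A [lifecycle_params()] object.
#' @param K Carrying capacity at the evaluation time (> 0).
#' @return Named numeric vector of derivatives (dE, dL, dP, dM per day).
#' @export
lifecycle_derivatives <- function(state, params, K) {
  s <- state_vec(state)
  dd <- density_dependent_rates(s[["E"]], s[["L"]], K, params)
  with(params, c(
    E = beta * s[["M"]] - s[["E"]] / d_E - dd$mu_E * s[["E"]],
    L = s[["E"]] / d_E - s[["L"]] / d_L - dd$mu_L * s[["L"]],
    P = s[["L"]] / d_L - s[["P"]] / d_P - mu_P * s[["P"]],
    M = female_fraction * s[["P"]] / d_P - mu_M * s[["M"]]
  ))
}

# Normalise the K(t) argument to a daily step-function forcing matrix
# covering [t0, t1]. Accepts a positive scalar, a function(t), or a
# two-column object (time, K).
k_forcing <- function(K_of_t, t_span) {
  tt <- seq(floor(t_span[1]) - 1, ceiling(t_span[2]) + 1, by = 1)
  if (is.function(K_of_t)) {
    kv <- vapply(tt, K_of_t, numeric(1))
  } else if (is.numeric(K_of_t) && length(K_of_t) == 1L) {
    kv <- rep(K_of_t, length(tt))
  } else {
    m <- as.matrix(as.data.frame(K_of_t))
    if (ncol(m) < 2) stop("K_of_t must be scalar, function(t), or (time, K) table")
    if (t_span[1] < min(m[, 1]) || t_span[2] > max(m[, 1]) + 1)
      stop("t_span extends outside the domain of the supplied K(t) series")
    idx <- findInterval(tt, m[, 1], all.inside = TRUE)
    kv <- m[idx, 2]
  }
  if (any(!is.finite(kv)) || any(kv <= 0))
    stop("carrying capacity K(t) must be finite and > 0 over the ",
         "integration span (apply the dry-season floor)")
  cbind(time = tt, K = kv)
}

# shared deSolve driver for the compiled RHS variants
integrate_compiled <- function(func, y0, parms, forc, times,
                               rtol = 1e-8, atol = 1e-10) {
  out <- try(deSolve::ode(
    y = y0, times = times, func = func, parms = parms,
    dllname = "gambiaedyn", initfunc = "mosq_initmod",
    initforc = "mosq_initforc", forcings = forc,
    fcontrol = list(method = "constant", rule = 2, f = 0),
    method = "lsoda", rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") ||
      attr(out, "istate")[1] < 0 ||
      nrow(out) < length(times))
    stop("ODE integration failed (solver did not complete the time span); ",
         "parameters: ", paste(signif(parms, 4), collapse = ", "))
  m <- unname(as.matrix(out)[, -1, drop = FALSE])
  neg <- m < 0
  if (any(neg)) {
    if (min(m[neg]) < -100 * atol)
      warning(sprintf("trajectory clipped at 0 (largest excursion %.3g)",
                      min(m[neg])))
    m[neg] <- 0
  }
  m
}

#' Simulate the mosquito lifecycle
#'
#' Integrates the lifecycle ODE system with a (possibly time-varying)
#' carrying capacity, using an adaptive stiff-capable solver
#' (`deSolve::lsoda` with a compiled right-hand side). `K(t)` is treated
#' as a daily step function, since rainfall — its driver — is recorded
#' daily and the carrying capacity can jump by orders of magnitude at the
#' onset of the rains. Tiny negative excursions are clipped to zero (with
#' a warning if they exceed solver tolerance).
#'
#' @param params A [lifecycle_params()] object.
#' @param K_of_t Carrying capacity: a positive scalar, a `function(t)`, or
#'   a two-column (time, K) table such as the output of
#'   [carrying_capacity_series()].
#' @param init Initial [lifecycle_state()].
#' @param t_span Length-2 numeric, start and end time in days.
#' @param dt_out Output step in days.
#' @param rtol,atol Solver tolerances.
#' @return A `mosq_sim` object: list with `times`, `states` (data frame
#'   with columns E, L, P, M) and `K_values` on the same grid.
#' @examples
#' p <- lifecycle_params()
#' sim <- simulate_lifecycle(p, K_of_t = 1e4,
#'                           init = lifecycle_state(M = 10),
#'                           t_span = c(0, 300))
#' tail(sim$states$M, 1)
#' @export
simulate_lifecycle <- function(params, K_of_t, init = lifecycle_state(M = 1),
                               t_span = c(0, 365), dt_out = 1,
                               rtol = 1e-8, atol = 1e-10) {
  forc <- k_forcing(K_of_t, t_span)
  times <- seq(t_span[1], t_span[2], by = dt_out)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  y0 <- state_vec(init)
  m <- integrate_compiled("mosq_base", y0, c_parms(params), forc, times,
                          rtol, atol)
  colnames(m) <- c("E", "L", "P", "M")
  kidx <- findInterval(times, forc[, 1], all.inside = TRUE)
  structure(list(times = times,
                 states = as.data.frame(m),
                 K_values = forc[kidx, 2],
                 params = params),
            class = "mosq_sim")
}

#' @export
print.mosq_sim <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<mosq_sim> %d time points over days [%.4g, %.4g]\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  final state: E = %.4g, L = %.4g, P = %.4g, M = %.4g\n",
              x$states$E[n], x$states$L[n], x$states$P[n], x$states$M[n]))
  invisible(x)
}

#' Equilibrium of the lifecycle model at constant carrying capacity
#'
#' At a constant carrying capacity the positive steady state can be
#' reduced to a single scalar condition: the effective reproduction
#' number equals one at the equilibrium scaled larval density
#' `x* = (E*+L*)/K`. Since the density-dependent rates depend on the
#' state only through `x`, `Reff(x)` is strictly decreasing and the root
#' is unique whenever the basic reproduction number exceeds one; it is
#' found by bracketed root-finding and back-substituted into the stage
#' balance equations. If `R0 <= 1` the only non-negative equilibrium is
#' extinction and the zero state is returned.
#'
#' Equilibrium densities scale linearly with `K`.
#'
#' @param params A [lifecycle_params()] object.
#' @param K Constant carrying capacity (> 0).
#' @return A [lifecycle_state()] at equilibrium.
#' @examples
#' p <- lifecycle_params()
#' eq <- lifecycle_equilibrium(p, K = 1e5)
#' max(abs(lifecycle_derivatives(eq, p, K = 1e5)))
#' @export
lifecycle_equilibrium <- function(params, K) {
  if (K <= 0) stop("K must be > 0")
  if (basic_reproduction_number(params) <= 1)
    return(lifecycle_state(0, 0, 0, 0))
  # Reff as a function of scaled density x = (E+L)/K
  reff_x <- function(x) {
    with(params, {
      muE <- mu_E0 * (1 + x)
      muL <- mu_L0 * (1 + gamma * x)
      female_fraction * (beta / mu_M) /
        ((1 + muE * d_E) * (1 + muL * d_L) * (1 + mu_P * d_P))
    })
  }
  hi <- 1
  while (reff_x(hi) > 1) hi <- hi * 4
  x <- stats::uniroot(function(z) reff_x(z) - 1, c(0, hi),
                      tol = .Machine$double.eps^0.75)$root
  with(params, {
    a_L <- 1 / d_L + mu_L0 * (1 + gamma * x)
    a_P <- 1 / d_P + mu_P
    # L = E / (d_E a_L); E + L = x K
    E <- x * K / (1 + 1 / (d_E * a_L))
    L <- E / (d_E * a_L)
    P <- L / (d_L * a_P)
    M <- female_fraction * P / (d_P * mu_M)
    lifecycle_state(E, L, P, M)
  })
}
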