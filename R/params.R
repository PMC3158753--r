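#' Lifecycle parameters for *Anopheles gambiae* s.l.
#'
#' Bundle of the biological rates and durations governing the
#' egg/larva/pupa/adult lifecycle model. Defaults are the posterior-median
#' estimates obtained by fitting the model to adult catch and rainfall data
#' from the Garki District of Nigeria, with priors from the entomological
#' literature; they describe a Sahelian *A. gambiae* s.l. population at
#' roughly 28 degrees C water temperature.
#'
#' @param beta Eggs laid per adult female per day.
#' @param d_E,d_L,d_P Mean durations (days) of the early-instar, late-instar
#'   and pupal stages. The reciprocal of each duration is the per-capita
#'   rate of progression to the next stage.
#' @param mu_E0,mu_L0 Daily per-capita mortality of early/late instars at
#'   very low larval density (1/day).
#' @param mu_P Daily pupal mortality (1/day); density independent.
#' @param mu_M Daily adult mortality (1/day); constant (no senescence).
#' @param gamma Relative strength of density-dependent mortality on late
#'   instars compared with early instars (dimensionless).
#' @param eps_max Maximum number of eggs per oviposition.
#' @param delta Duration of the gonotrophic cycle (days).
#' @param female_fraction Proportion of emerging adults that are female.
#'
#' @return An object of class `lifecycle_params` (a named list).
#' @seealso [oviposition_rate()], [basic_reproduction_number()],
#'   [simulate_lifecycle()]
#' @examples
#' p <- lifecycle_params()
#' basic_reproduction_number(p)
#' @export
lifecycle_params <- function(beta = 21.19,
                             d_E = 6.64, d_L = 3.72, d_P = 0.64,
                             mu_E0 = 0.034, mu_L0 = 0.035,
                             mu_P = 0.25, mu_M = 0.096,
                             gamma = 13.25,
                             eps_max = 93.6, delta = 3,
                             female_fraction = 0.5) {
  p <- list(beta = beta, d_E = d_E, d_L = d_L, d_P = d_P,
            mu_E0 = mu_E0, mu_L0 = mu_L0, mu_P = mu_P, mu_M = mu_M,
            gamma = gamma, eps_max = eps_max, delta = delta,
            female_fraction = female_fraction)
  validate_lifecycle_params(p)
  structure(p, class = "lifecycle_params")
}

validate_lifecycle_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all lifecycle parameters must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "))
  pos <- c("beta", "d_E", "d_L", "d_P", "mu_E0", "mu_L0", "mu_P", "mu_M",
           "eps_max", "delta")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("lifecycle parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (p$gamma < 0) stop("gamma must be >= 0")
  if (p$female_fraction <= 0 || p$female_fraction > 1)
    stop("female_fraction must lie in (0, 1]")
  bmax <- p$eps_max * p$mu_M / (exp(p$delta * p$mu_M) - 1)
  if (p$beta > bmax * (1 + 1e-8))
    warning(sprintf(
      "beta = %.3f exceeds the oviposition upper bound beta_max = %.3f implied by eps_max, delta and mu_M",
      p$beta, bmax))
  invisible(p)
}

#' @export
print.lifecycle_params <- function(x, ...) {
  cat("<lifecycle_params>\n")
  cat(sprintf("  oviposition beta = %.3f eggs/female/day (gonotrophic cycle %.3g d, eps_max %.1f)\n",
              x$beta, x$delta, x$eps_max))
  cat(sprintf("  stage durations  d_E = %.3g, d_L = %.3g, d_P = %.3g days\n",
              x$d_E, x$d_L, x$d_P))
  cat(sprintf("  mortalities      mu_E0 = %.3g, mu_L0 = %.3g, mu_P = %.3g, mu_M = %.3g /day\n",
              x$mu_E0, x$mu_L0, x$mu_P, x$mu_M))
  cat(sprintf("  density dep.     gamma = %.3g; female fraction = %.3g\n",
              x$gamma, x$female_fraction))
  cat(sprintf("  R0 = %.2f\n", basic_reproduction_number(x)))
  invisible(x)
}

#' Lifecycle state (compartment densities)
#'
#' State of the lifecycle model: densities of early instars `E`, late
#' instars `L`, pupae `P` and adult females `M` (non-negative, on an
#' arbitrary but consistent per-site scale).
#'
#' @param E,L,P,M Non-negative compartment densities.
#' @return A named numeric vector of class `lifecycle_state`.
#' @export
lifecycle_state <- function(E = 0, L = 0, P = 0, M = 0) {
  s <- c(E = unname(E), L = unname(L), P = unname(P), M = unname(M))
  if (!all(is.finite(s))) stop("lifecycle state must be finite")
  if (any(s < 0)) stop("lifecycle state components must be >= 0")
  structure(s, class = c("lifecycle_state", "numeric"))
}

# internal: strip class, keep names
state_vec <- function(s) {
  v <- unclass(s)[c("E", "L", "P", "M")]
  if (any(is.na(v))) stop("state must carry components E, L, P, M")
  v
}

# parameter vector handed to the compiled RHS (12 slots)
c_parms <- function(p, xtra = 0, cov = 0) {
  c(p$beta, p$d_E, p$d_L, p$d_P, p$mu_E0, p$mu_L0, p$mu_P, p$mu_M,
    p$gamma, p$female_fraction, xtra, cov)
}
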