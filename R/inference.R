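#' Catch data (nightly adult collections)
#'
#' Village-level counts of adult mosquitoes collected per sampling night
#' (e.g. pyrethrum spray catches of indoor-resting mosquitoes).
#'
#' @param date Sampling dates (`Date`).
#' @param village Village identifiers (character or coercible).
#' @param count Non-negative integer counts.
#' @return A `catch_data` data frame with columns `date`, `village`,
#'   `count`.
#' @export
catch_data <- function(date, village, count) {
  date <- as.Date(date)
  if (any(!is.finite(count)) || any(count < 0) ||
      any(count != round(count)))
    stop("counts must be non-negative integers")
  structure(data.frame(date = date, village = as.character(village),
                       count = as.integer(count)),
            class = c("catch_data", "data.frame"))
}

# ---- priors ---------------------------------------------------------------

# Fit a prior family to a reported median and 95% interval. Every
# published interval here is symmetric on the natural scale (the mean of
# the bounds reproduces the reported median to within a few percent), so
# the family is a normal matched to the bounds, truncated to positive
# support when the parameter is a positive rate or duration.
fit_prior <- function(median, lo, hi) {
  stopifnot(hi > lo, median > lo, median < hi)
  mid <- (lo + hi) / 2
  if (abs(mid / median - 1) > 0.05)
    warning(sprintf(
      "interval (%g, %g) is not symmetric about the median %g; bounds win",
      lo, hi, median))
  list(dist = "tnorm", par1 = mid, par2 = (hi - lo) / (2 * stats::qnorm(0.975)),
       median = median, lo = lo, hi = hi)
}

prior_logdens <- function(pr, x) {
  switch(pr$dist,
    tnorm = ifelse(x > 0, stats::dnorm(x, pr$par1, pr$par2, log = TRUE), -Inf),
    lnorm = stats::dlnorm(x, pr$par1, pr$par2, log = TRUE),
    logunif = ifelse(x >= pr$par1 & x <= pr$par2,
                     -log(x) - log(log(pr$par2 / pr$par1)), -Inf),
    stop("unknown prior family ", pr$dist))
}

# nominal quantiles of the fitted family (for tnorm, of the parent
# normal: the truncation at 0 removes at most ~2% mass for the widest
# prior and the nominal interval is the published one)
prior_quantile <- function(pr, p) {
  switch(pr$dist,
    tnorm = stats::qnorm(p, pr$par1, pr$par2),
    lnorm = stats::qlnorm(p, pr$par1, pr$par2),
    logunif = pr$par1 * (pr$par2 / pr$par1)^p)
}

prior_sample <- function(pr, n) {
  x <- prior_quantile(pr, stats::runif(n))
  if (pr$dist == "tnorm") {
    bad <- x <= 0
    while (any(bad)) {
      x[bad] <- prior_quantile(pr, stats::runif(sum(bad)))
      bad <- x <= 0
    }
  }
  x
}

#' Default priors for the lifecycle and observation parameters
#'
#' Literature-based priors: stage durations and low-density mortalities
#' from laboratory studies of *A. gambiae* development and survival,
#' adult mortality from Sahelian field estimates, oviposition and
#' density-dependence from natural breeding-site life tables, and
#' rainfall memory from rainfall-abundance regressions. Each prior is a
#' positive-support family matched to the published median and 95%
#' interval (log-normal where the interval is symmetric on the log
#' scale, gamma otherwise). The observation-layer parameters get weak
#' defaults: dispersion `r` log-normal with median 1, village scaling
#' factors `lam` log-uniform over a broad range.
#'
#' @return A named list of prior specifications (class `prior_spec`);
#'   entries `d_E, d_L, d_P, mu_E0, mu_L0, mu_P, mu_M, beta, gamma, tau,
#'   r, lam`.
#' @export
default_priors <- function() {
  pr <- list(
    d_E   = fit_prior(6.67, 4.64, 8.69),
    d_L   = fit_prior(4.17, 1.88, 6.46),
    d_P   = fit_prior(1.0, 0.20, 1.80),
    mu_E0 = fit_prior(0.035, 0.025, 0.044),
    mu_L0 = fit_prior(0.035, 0.025, 0.044),
    mu_P  = fit_prior(0.25, 0.18, 0.32),
    mu_M  = fit_prior(0.091, 0.082, 0.101),
    beta  = fit_prior(12.75, 0.64, 24.86),
    gamma = fit_prior(13.06, 9.53, 17.36),
    tau   = fit_prior(7, 3.5, 11),
    r     = list(dist = "lnorm", par1 = 0, par2 = log(10) / stats::qnorm(0.975),
                 median = 1, lo = 0.1, hi = 10),
    lam   = list(dist = "logunif", par1 = 1e-4, par2 = 1e6,
                 median = 10, lo = 1e-4, hi = 1e6)
  )
  structure(pr, class = "prior_spec")
}

#' Log prior density
#'
#' Sum of independent per-parameter log densities under a prior
#' specification; `-Inf` outside the support. Village scaling factors
#' (named `lam_<village>`) use the `lam` prior.
#'
#' @param theta Named numeric vector of parameter values (natural scale).
#' @param priors A `prior_spec`, e.g. [default_priors()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors) {
  tot <- 0
  for (nm in names(theta)) {
    key <- if (startsWith(nm, "lam")) "lam" else nm
    pr <- priors[[key]]
    if (is.null(pr)) stop("no prior specified for parameter ", nm)
    tot <- tot + prior_logdens(pr, theta[[nm]])
  }
  tot
}

# ---- likelihood -----------------------------------------------------------

# canonicalise (catches, rainfall) into per-village blocks with
# day-since-rainfall-start observation indices
assemble_villages <- function(catches, rainfall) {
  stopifnot(inherits(catches, "data.frame"))
  vs <- sort(unique(catches$village))
  if (inherits(rainfall, "rainfall_series"))
    rainfall <- stats::setNames(rep(list(rainfall), length(vs)), vs)
  lapply(stats::setNames(vs, vs), function(v) {
    rs <- rainfall[[v]]
    if (is.null(rs)) stop("no rainfall series supplied for village ", v)
    sub <- catches[catches$village == v, ]
    days <- as.numeric(as.Date(sub$date) - rs$date[1])
    if (any(days < 0) || any(days > nrow(rs) - 1))
      stop("catch dates outside the rainfall series span for village ", v)
    list(village = v, rainfall = rs, days = days, counts = sub$count)
  })
}

#' Negative binomial log-likelihood of catch data
#'
#' Likelihood of nightly adult catches given the lifecycle model: for
#' each village the model is driven by that village's rainfall-derived
#' carrying capacity, the predicted adult density `M(t, i)` on each
#' sampling night is the negative binomial mean, and dispersion `r`
#' captures the overdispersion of the catches (smaller `r`, more
#' overdispersed). The village scaling factor in each `cc_config`
#' absorbs both breeding-habitat scale and catching effort, so no
#' separate per-house offset is applied. If the ODE integration fails at
#' the proposed parameters the function returns `-Inf` (the proposal is
#' rejected).
#'
#' @param params A [lifecycle_params()] object.
#' @param catches A [catch_data()] frame.
#' @param rainfall A [rainfall_series()] shared by all villages, or a
#'   named list of series (one per village).
#' @param cc A [cc_config()] shared by all villages, or a named list.
#'   Its `K_floor` should already hold the dry-season floor.
#' @param r Negative binomial dispersion (> 0).
#' @param sim_rtol,sim_atol Solver tolerances used inside the likelihood.
#' @return Scalar log-likelihood.
#' @export
negbin_loglik <- function(params, catches, rainfall, cc, r,
                          sim_rtol = 1e-6, sim_atol = 1e-8) {
  stopifnot(r > 0)
  blocks <- assemble_villages(catches, rainfall)
  if (inherits(cc, "cc_config"))
    cc <- stats::setNames(rep(list(cc), length(blocks)), names(blocks))
  tot <- 0
  for (b in blocks) {
    cfg <- cc[[b$village]]
    if (is.null(cfg)) stop("no cc_config for village ", b$village)
    mu <- tryCatch({
      kser <- carrying_capacity_series(b$rainfall, cfg)
      init <- lifecycle_equilibrium(params, kser[1, "K"])
      days <- sort(unique(round(b$days)))
      times <- if (days[1] > 0) c(0, days) else days
      forc <- k_forcing(kser, c(0, max(days)))
      m <- integrate_compiled("mosq_base", state_vec(init),
                              c_parms(params), forc, times,
                              sim_rtol, sim_atol)
      m[match(round(b$days), times), 4]
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(mu) || anyNA(mu)) return(-Inf)
    tot <- tot + sum(stats::dnbinom(b$counts, size = r,
                                    mu = pmax(mu, 1e-10), log = TRUE))
  }
  tot
}

# ---- MCMC -----------------------------------------------------------------

# adaptive random-walk Metropolis on an unconstrained vector;
# per-component proposal sds adapted towards 23.4% acceptance during
# burn-in (Robbins-Monro on a global scale plus running component sds),
# frozen afterwards to preserve detailed balance.
rw_metropolis <- function(log_post, init, n_iter, burn,
                          target = 0.234, init_sd = 0.1) {
  d <- length(init)
  phi <- init
  lp <- log_post(phi)
  if (!is.finite(lp)) stop("initial point has non-finite log posterior")
  scale <- 1
  sds <- rep(init_sd, d)
  run_mean <- phi; run_var <- rep(init_sd^2, d)
  total <- burn + n_iter
  out <- matrix(NA_real_, n_iter, d,
                dimnames = list(NULL, names(init)))
  lps <- numeric(n_iter)
  acc <- 0L
  for (i in seq_len(total)) {
    prop <- phi + stats::rnorm(d, 0, scale * sds)
    lp_prop <- log_post(prop)
    accept <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
    if (accept) { phi <- prop; lp <- lp_prop }
    if (i <= burn) {
      gain <- min(0.25, 2 / sqrt(i))
      scale <- scale * exp(gain * ((if (accept) 1 else 0) - target))
      dlt <- phi - run_mean
      run_mean <- run_mean + dlt / (i + 1)
      run_var <- run_var + (dlt * (phi - run_mean) - run_var) / (i + 1)
      if (i > 50) sds <- pmax(sqrt(run_var), 1e-4)
    } else {
      j <- i - burn
      out[j, ] <- phi
      lps[j] <- lp
      acc <- acc + accept
    }
  }
  list(samples = out, lp = lps, acceptance = acc / n_iter)
}

lifecycle_param_names <- c("d_E", "d_L", "d_P", "mu_E0", "mu_L0",
                           "mu_P", "mu_M", "beta", "gamma")

# build a lifecycle_params object from a named value vector plus defaults,
# without triggering constructor warnings mid-chain
params_from_theta <- function(theta, base) {
  p <- unclass(base)
  for (nm in intersect(names(theta), lifecycle_param_names))
    p[[nm]] <- theta[[nm]]
  structure(p, class = "lifecycle_params")
}

#' Fit the lifecycle model to catch and rainfall data by MCMC
#'
#' Bayesian fitting: an adaptive random-walk Metropolis sampler on
#' log-transformed parameters, targeting the posterior formed by the
#' negative binomial catch likelihood ([negbin_loglik()]) and the
#' literature priors ([default_priors()]). The dry-season
#' carrying-capacity floor is recomputed at every proposal from the
#' proposed lifecycle parameters and dispersion (detectability 0.2), so
#' it is always consistent with the sampled parameter set.
#'
#' @param catches A [catch_data()] frame.
#' @param rainfall A [rainfall_series()] or named list of series per
#'   village.
#' @param priors A `prior_spec`; defaults to [default_priors()].
#' @param model Rainfall-to-carrying-capacity model (see [cc_config()]).
#' @param fit_params Character vector naming the parameters to sample.
#'   Any of the lifecycle parameters, `tau`, `r`, and per-village scaling
#'   factors `lam_<village>` (the token `"lam"` expands to all
#'   villages). Parameters not listed are fixed at `fixed` (or the prior
#'   median).
#' @param fixed Named numeric vector of values for non-sampled
#'   parameters (overrides prior medians).
#' @param n_iter Retained iterations (post burn-in).
#' @param burn Burn-in iterations (adaptation window).
#' @param seed Integer seed; the chain is reproducible given the seed.
#' @param init Optional named vector of starting values (natural scale).
#' @param detect_prob Dry-season detectability used for the K floor.
#' @param sim_rtol,sim_atol Solver tolerances inside the likelihood.
#' @return A `posterior_chain`: list with `samples` (matrix, natural
#'   scale), `lp` (log posterior), `loglik`, `acceptance`, and the fit
#'   setup (`fixed`, `model`, `priors`, `catches`, `rainfall`,
#'   `villages`, `detect_prob`, `seed`).
#' @export
run_mcmc <- function(catches, rainfall, priors = default_priors(),
                     model = "exponential",
                     fit_params = c("beta", "gamma", "tau", "lam", "r"),
                     fixed = NULL,
                     n_iter = 50000, burn = 1000, seed = 1,
                     init = NULL, detect_prob = 0.2,
                     sim_rtol = 1e-6, sim_atol = 1e-8) {
  blocks <- assemble_villages(catches, rainfall)
  villages <- names(blocks)
  if (length(blocks) < 1 || all(vapply(blocks, function(b)
    length(b$counts), integer(1)) < 2))
    stop("need at least one village with >= 2 observations")
  if ("lam" %in% fit_params)
    fit_params <- c(setdiff(fit_params, "lam"),
                    paste0("lam_", villages))

  # defaults for everything, fitted or not
  base_vals <- vapply(c(lifecycle_param_names, "tau", "r"),
                      function(nm) priors[[nm]]$median, numeric(1))
  base_params <- params_from_theta(base_vals, lifecycle_params())
  # rough data-driven scale for lam: match mean positive catch to the
  # equilibrium adult density at the mean wet-period carrying capacity
  slope <- lifecycle_equilibrium(base_params, 1e4)[["M"]] / 1e4
  lam_guess <- vapply(blocks, function(b) {
    wr <- mean(b$rainfall$rain_mm[b$rainfall$rain_mm > 0])
    if (!is.finite(wr) || wr <= 0) wr <- 1
    max(mean(b$counts), 0.5) / (slope * wr)
  }, numeric(1))
  defaults <- c(base_vals, stats::setNames(lam_guess,
                                           paste0("lam_", villages)))
  if (!is.null(fixed)) defaults[names(fixed)] <- fixed
  unknown <- setdiff(fit_params, names(defaults))
  if (length(unknown)) stop("unknown fit parameters: ",
                            paste(unknown, collapse = ", "))

  theta0 <- defaults[fit_params]
  if (!is.null(init)) theta0[names(init)] <- init

  lam_names <- paste0("lam_", villages)
  log_post_phi <- function(phi) {
    theta <- exp(phi)
    full <- defaults
    full[fit_params] <- theta
    lprior <- log_prior(stats::setNames(theta, fit_params), priors) +
      sum(phi)  # Jacobian of the log transform
    if (!is.finite(lprior)) return(-Inf)
    p <- params_from_theta(full, base_params)
    r <- full[["r"]]
    kf <- tryCatch(dry_season_floor(p, r, detect_prob),
                   error = function(e) NULL)
    if (is.null(kf)) return(-Inf)
    ccs <- lapply(stats::setNames(lam_names, villages), function(ln)
      cc_config(model, tau = full[["tau"]], lam = full[[ln]],
                K_floor = kf))
    ll <- negbin_loglik(p, catches, rainfall, ccs, r,
                        sim_rtol = sim_rtol, sim_atol = sim_atol)
    lprior + ll
  }

  set.seed(as.integer(seed))
  res <- rw_metropolis(log_post_phi, log(theta0), n_iter, burn)
  samples <- exp(res$samples)
  colnames(samples) <- fit_params
  # recompute loglik for retained unique states (cheap: only on change)
  lls <- rep(NA_real_, n_iter)
  prev_key <- NULL
  for (j in seq_len(n_iter)) {
    key <- res$samples[j, ]
    if (!is.null(prev_key) && identical(key, prev_key)) {
      lls[j] <- lls[j - 1]
    } else {
      theta <- exp(key)
      lls[j] <- res$lp[j] -
        (log_prior(stats::setNames(theta, fit_params), priors) + sum(key))
    }
    prev_key <- key
  }
  structure(list(samples = samples, lp = res$lp, loglik = lls,
                 acceptance = res$acceptance,
                 fit_params = fit_params, fixed = defaults,
                 model = model, priors = priors, catches = catches,
                 rainfall = rainfall, villages = villages,
                 detect_prob = detect_prob, seed = seed),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("<posterior_chain> %d samples, %d parameters, acceptance %.1f%%\n",
              nrow(x$samples), ncol(x$samples), 100 * x$acceptance))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior summary (medians and 95% credible intervals)
#'
#' Equal-tailed quantile summary of a posterior chain.
#'
#' @param chain A `posterior_chain` (or a samples matrix).
#' @param probs Quantiles to report.
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(chain, probs = c(0.025, 0.5, 0.975)) {
  m <- if (inherits(chain, "posterior_chain")) chain$samples else as.matrix(chain)
  q <- t(apply(m, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(parameter = colnames(m), q)
  names(out)[-1] <- c("lo", "median", "hi")[seq_along(probs)]
  rownames(out) <- NULL
  out
}

#' Credible envelope for the adult-density trajectory
#'
#' Repeatedly samples parameter sets from the joint posterior, simulates
#' the adult trajectory for one village, and returns pointwise quantile
#' bands (2.5/25/50/75/97.5%), the standard inter-quartile plus 95%
#' envelope display.
#'
#' @param chain A `posterior_chain` from [run_mcmc()].
#' @param village Village to simulate (default: first fitted village).
#' @param n_draws Number of posterior draws.
#' @param seed Seed for the draw indices.
#' @return Data frame `time, q025, q25, q50, q75, q975`.
#' @export
credible_envelope <- function(chain, village = chain$villages[1],
                              n_draws = 100, seed = 1) {
  stopifnot(inherits(chain, "posterior_chain"))
  rf <- chain$rainfall
  rs <- if (inherits(rf, "rainfall_series")) rf else rf[[village]]
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(chain$samples), n_draws, replace = TRUE)
  lam_nm <- paste0("lam_", village)
  trajs <- vapply(idx, function(i) {
    full <- chain$fixed
    full[chain$fit_params] <- chain$samples[i, ]
    p <- params_from_theta(full, lifecycle_params())
    kf <- dry_season_floor(p, full[["r"]], chain$detect_prob)
    cfg <- cc_config(chain$model, tau = full[["tau"]],
                     lam = full[[lam_nm]], K_floor = kf)
    kser <- carrying_capacity_series(rs, cfg)
    init <- lifecycle_equilibrium(p, kser[1, "K"])
    sim <- simulate_lifecycle(p, kser, init,
                              t_span = c(0, nrow(rs) - 1), dt_out = 1,
                              rtol = 1e-6, atol = 1e-8)
    sim$states$M
  }, numeric(nrow(rs)))
  q <- apply(trajs, 1, stats::quantile,
             probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  out <- data.frame(time = 0:(nrow(rs) - 1), t(q))
  names(out)[-1] <- c("q025", "q25", "q50", "q75", "q975")
  out
}

#' Compare rainfall-to-carrying-capacity models
#'
#' Ranks fitted chains (one per rainfall weighting model) by the
#' deviance information criterion, `DIC = mean(D) + var(D)/2` with
#' `D = -2 log L`, and also reports a posterior-predictive aggregate log
#' score (`log mean exp` of the retained log-likelihoods). Lower DIC and
#' higher log score indicate better fit.
#'
#' @param chains Named list of `posterior_chain` objects.
#' @return Data frame `model, DIC, pD, log_score, rank` sorted by DIC.
#' @export
model_compare <- function(chains) {
  stopifnot(length(chains) >= 1)
  rows <- lapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    D <- -2 * ch$loglik
    ll <- ch$loglik
    lse <- max(ll) + log(mean(exp(ll - max(ll))))
    data.frame(model = nm, DIC = mean(D) + stats::var(D) / 2,
               pD = stats::var(D) / 2, log_score = lse)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$DIC), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
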