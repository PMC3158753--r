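test_that("fitted prior families reproduce the published 95% bounds", {
  pr <- default_priors()
  for (nm in c("d_E", "d_L", "d_P", "mu_E0", "mu_L0", "mu_P", "mu_M",
               "beta", "gamma", "tau")) {
    q <- gambiaedyn:::prior_quantile(pr[[nm]], c(0.025, 0.975))
    expect_equal(q[1], pr[[nm]]$lo, tolerance = 0.02)
    expect_equal(q[2], pr[[nm]]$hi, tolerance = 0.02)
    # and the implied centre sits close to the published median
    expect_equal(gambiaedyn:::prior_quantile(pr[[nm]], 0.5),
                 pr[[nm]]$median, tolerance = 0.05)
  }
})

test_that("log prior is finite at the medians and -Inf off support", {
  pr <- default_priors()
  theta <- c(beta = 12.75, gamma = 13.06, tau = 7, r = 1, lam_v1 = 10)
  expect_true(is.finite(log_prior(theta, pr)))
  expect_identical(log_prior(c(mu_M = -0.1), pr), -Inf)
  expect_identical(log_prior(c(lam_v9 = 1e12), pr), -Inf)
  expect_error(log_prior(c(nonsense = 1), pr), "no prior")
})

test_that("negative binomial likelihood matches the closed form at a zero count", {
  st <- small_study(seed = 3, lam = 10)
  rs <- st$rainfall$v1
  p <- st$scenario$params
  kf <- dry_season_floor(p, 1)
  cfg <- cc_config("exponential", 4, 10, kf)
  # predicted mean on day 30 (dry season)
  kser <- carrying_capacity_series(rs, cfg)
  init <- lifecycle_equilibrium(p, kser[1, "K"])
  sim <- simulate_lifecycle(p, kser, init, t_span = c(0, 40))
  mu <- sim$states$M[sim$times == 30]
  one_zero <- catch_data(rs$date[1] + 30, "v1", 0L)
  r <- 1.7
  ll <- negbin_loglik(p, one_zero, rs, cfg, r, sim_rtol = 1e-8,
                      sim_atol = 1e-10)
  expect_equal(ll, r * log(r / (r + mu)), tolerance = 1e-6)
})

test_that("the negative binomial likelihood approaches Poisson as r grows", {
  st <- small_study(seed = 3, lam = 10)
  p <- st$scenario$params
  kf <- dry_season_floor(p, 1e6)
  cfg <- cc_config("exponential", 4, 10, kf)
  ct <- st$catches[st$catches$village == "v1", ]
  ct <- catch_data(ct$date, ct$village, ct$count)
  ll_nb <- negbin_loglik(p, ct, st$rainfall$v1, cfg, r = 1e6,
                         sim_rtol = 1e-8, sim_atol = 1e-10)
  # Poisson oracle with the same predicted means
  rs <- st$rainfall$v1
  kser <- carrying_capacity_series(rs, cfg)
  init <- lifecycle_equilibrium(p, kser[1, "K"])
  sim <- simulate_lifecycle(p, kser, init, t_span = c(0, nrow(rs) - 1),
                            rtol = 1e-8, atol = 1e-10)
  days <- as.numeric(ct$date - rs$date[1])
  mu <- pmax(sim$states$M[match(days, sim$times)], 1e-10)
  expect_equal(ll_nb, sum(dpois(ct$count, mu, log = TRUE)),
               tolerance = 1e-4)
})

test_that("the likelihood is invariant to village relabelling", {
  st <- small_study(seed = 5, lam = c(10, 25))
  p <- st$scenario$params
  kf <- dry_season_floor(p, 1)
  cc <- list(v1 = cc_config("exponential", 4, 10, kf),
             v2 = cc_config("exponential", 4, 25, kf))
  ll1 <- negbin_loglik(p, st$catches, st$rainfall, cc, 1)
  # swap labels everywhere consistently
  swap <- c(v1 = "v2", v2 = "v1")
  ct2 <- catch_data(st$catches$date, swap[st$catches$village],
                    st$catches$count)
  rf2 <- list(v1 = st$rainfall$v2, v2 = st$rainfall$v1)
  cc2 <- list(v1 = cc$v2, v2 = cc$v1)
  ll2 <- negbin_loglik(p, ct2, rf2, cc2, 1)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("the Metropolis sampler recovers a known target (prior recovery)", {
  # constant-likelihood sanity check: sampling the mu_M prior through the
  # log-transformed random-walk kernel must return the prior itself
  pr <- default_priors()$mu_M
  log_post <- function(phi)
    gambiaedyn:::prior_logdens(pr, exp(phi)) + phi
  set.seed(123)
  out <- gambiaedyn:::rw_metropolis(log_post, log(0.09), n_iter = 1e4,
                                    burn = 1000)
  x <- exp(out$samples[, 1])
  ks <- suppressWarnings(
    ks.test(x, function(q) pnorm(q, pr$par1, pr$par2)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("chains are reproducible given a seed", {
  st <- small_study(seed = 11, lam = 10)
  ch1 <- run_mcmc(st$catches, st$rainfall, n_iter = 40, burn = 30, seed = 4,
                  fit_params = c("beta", "lam", "r"))
  ch2 <- run_mcmc(st$catches, st$rainfall, n_iter = 40, burn = 30, seed = 4,
                  fit_params = c("beta", "lam", "r"))
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$lp, ch2$lp)
  ch3 <- run_mcmc(st$catches, st$rainfall, n_iter = 40, burn = 30, seed = 5,
                  fit_params = c("beta", "lam", "r"))
  expect_false(identical(ch1$samples, ch3$samples))
  # retained samples never carry an impossible posterior
  expect_true(all(is.finite(ch1$lp)))
  expect_true(all(is.finite(ch1$loglik)))
})

test_that("posterior summaries are equal-tailed quantiles", {
  chain <- matrix(c(rep(3.5, 100), rnorm(100)), ncol = 2,
                  dimnames = list(NULL, c("const", "sym")))
  s <- posterior_summary(chain)
  expect_equal(s$median[1], 3.5)
  expect_equal(s$lo[1], 3.5)
  expect_equal(s$hi[1], 3.5)
  # sort-based oracle (type-7 interpolation on the order statistics)
  x <- sort(chain[, 2])
  oracle <- function(p) {
    h <- (length(x) - 1) * p
    lo <- floor(h) + 1
    x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(s$lo[2], oracle(0.025))
  expect_equal(s$median[2], oracle(0.5))
  expect_equal(s$hi[2], oracle(0.975))
})

test_that("credible envelopes bracket the median-parameter trajectory", {
  st <- small_study(seed = 2, lam = 10)
  ch <- run_mcmc(st$catches, st$rainfall, n_iter = 150, burn = 150, seed = 9,
                 fit_params = c("beta", "lam", "r"))
  env <- credible_envelope(ch, n_draws = 25, seed = 1)
  expect_true(all(env$q025 <= env$q25 & env$q25 <= env$q50 &
                    env$q50 <= env$q75 & env$q75 <= env$q975))
  # the trajectory at the posterior-median parameters lies in the band
  med <- apply(ch$samples, 2, stats::median)
  full <- ch$fixed
  full[ch$fit_params] <- med
  p <- gambiaedyn:::params_from_theta(full, lifecycle_params())
  kf <- dry_season_floor(p, full[["r"]])
  cfg <- cc_config(ch$model, tau = full[["tau"]], lam = full[["lam_v1"]],
                   K_floor = kf)
  rs <- st$rainfall$v1
  kser <- carrying_capacity_series(rs, cfg)
  sim <- simulate_lifecycle(p, kser, lifecycle_equilibrium(p, kser[1, "K"]),
                            t_span = c(0, nrow(rs) - 1))
  inside <- mean(sim$states$M >= env$q025 & sim$states$M <= env$q975)
  expect_gt(inside, 0.95)
})

test_that("posterior width for beta shrinks with more data", {
  sc <- synthetic_scenario(lam = 15, r = 2, seed = 21)
  rf <- generate_rainfall(sc, seed = 21)
  ct1 <- generate_catches(sc, rf, sampling_days = seq(10, 360, by = 14),
                          seed = 22)
  ct4 <- generate_catches(sc, rf, sampling_days = seq(3, 363, by = 3),
                          seed = 23)
  fitp <- c("beta", "lam", "r")
  fx <- c(tau = 4, gamma = 13.25)  # generating values for the nuisances
  ch1 <- run_mcmc(ct1, rf, n_iter = 800, burn = 400, seed = 1,
                  fit_params = fitp, fixed = fx)
  ch4 <- run_mcmc(ct4, rf, n_iter = 800, burn = 400, seed = 1,
                  fit_params = fitp, fixed = fx)
  w <- function(ch) {
    s <- posterior_summary(ch)
    s$hi[s$parameter == "beta"] - s$lo[s$parameter == "beta"]
  }
  expect_lt(w(ch4), w(ch1))
})

test_that("model comparison ties identical chains and ranks by DIC", {
  st <- small_study(seed = 13, lam = 10)
  ch <- run_mcmc(st$catches, st$rainfall, n_iter = 100, burn = 100,
                 seed = 2, fit_params = c("lam", "r"))
  cmp <- model_compare(list(a = ch, b = ch))
  expect_equal(cmp$DIC[1], cmp$DIC[2])
  expect_equal(sort(cmp$rank), 1:2)
})
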