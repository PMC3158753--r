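test_that("zero-coverage adult interventions are the identity transform", {
  p <- field_params()
  out <- adult_intervention_effects(p, adult_intervention_params())
  expect_equal(unclass(out), unclass(p))
})

test_that("pure killing raises adult mortality without touching the cycle", {
  p <- field_params()
  iv <- adult_intervention_params(llin_coverage = 1, llin_kill = 0.3,
                                  llin_repel = 0)
  out <- adult_intervention_effects(p, iv)
  expect_gt(out$mu_M, p$mu_M)
  expect_equal(out$delta, p$delta)
  expect_lt(out$beta, p$beta)  # dying before feeding costs eggs
})

test_that("a repel-only net lowers oviposition without extra mortality", {
  p <- field_params()
  iv <- adult_intervention_params(llin_coverage = 0.5, llin_kill = 0,
                                  llin_repel = 0.4,
                                  gonotrophic_extension = 0.5)
  out <- adult_intervention_effects(p, iv)
  expect_equal(out$mu_M, p$mu_M)
  # cycle-extension arithmetic: w = 0.5 * 0.4 per attempt
  w <- 0.5 * 0.4
  delta2 <- p$delta + 0.5 * w / (1 - w)
  expect_equal(out$delta, delta2)
  eps_eff <- p$beta * (exp(p$delta * p$mu_M) - 1) / p$mu_M
  expect_equal(out$beta, eps_eff * p$mu_M / (exp(delta2 * p$mu_M) - 1))
  expect_lt(out$beta, p$beta)
})

test_that("untreated larvicide runs collapse onto the base model", {
  p <- field_params()
  eq <- lifecycle_equilibrium(p, 1e4)
  base <- simulate_lifecycle(p, 1e4, eq, c(0, 400), dt_out = 20)
  lv0 <- simulate_larvicide(p, larvicide_params(55.2, 0), 1e4, eq,
                            c(0, 400), dt_out = 20)
  expect_equal(lv0$states$M, base$states$M, tolerance = 1e-8)
  expect_equal(lv0$states$E, base$states$E, tolerance = 1e-8)
  expect_true(all(lv0$states$E_T == 0))
  # a neutral treatment (upsilon = 1) at any coverage changes nothing
  lv1 <- simulate_larvicide(p, larvicide_params(1, 0.6), 1e4, eq,
                            c(0, 400), dt_out = 20)
  expect_equal(lv1$states$M, base$states$M, tolerance = 1e-7)
  # treated + untreated compartments then hold the same totals as base
  expect_equal(lv1$states$E + lv1$states$E_T, base$states$E,
               tolerance = 1e-7)
})

test_that("per-egg emergence in a treated site falls by ~99% (pulse oracle)", {
  # dynamic check of the survival calculus: inject a pulse of eggs into a
  # fully treated vs untreated site at low density and integrate the
  # emergence flux; compare with the closed-form stage-survival product
  p <- field_params()
  emergence <- function(upsilon) {
    p0 <- suppressWarnings(lifecycle_params(beta = 1e-12))
    sim <- simulate_larvicide(p0, larvicide_params(max(upsilon, 1), 1),
                              1e12, c(0, 0, 0, 1, 0, 0, 0),
                              c(0, 400), dt_out = 0.1, atol = 1e-14)
    # integrated emergence flux leaving treated pupae
    sum(sim$states$P_T / p0$d_P) * 0.1
  }
  surv_untreated <- emergence(1)
  surv_treated <- emergence(55.2)
  expect_equal(surv_untreated, egg_to_adult_survival(p), tolerance = 1e-3)
  analytic <- with(p, 1 / ((1 + 55.2 * mu_E0 * d_E) *
                           (1 + 55.2 * mu_L0 * d_L) *
                           (1 + 55.2 * mu_P * d_P)))
  expect_equal(surv_treated, analytic, tolerance = 1e-3)
  expect_equal(100 * (1 - surv_treated / surv_untreated), 99.85,
               tolerance = 0.01)
})

test_that("pupacide identities: F = 0 is the base model, F = 1 stops recruitment", {
  p <- field_params()
  eq <- lifecycle_equilibrium(p, 1e4)
  base <- simulate_lifecycle(p, 1e4, eq, c(0, 400), dt_out = 20)
  pv0 <- simulate_pupacide(p, pupacide_params(0, 0.5), 1e4, eq,
                           c(0, 400), dt_out = 20)
  expect_equal(pv0$states$M, base$states$M, tolerance = 1e-7)
  # full coverage, full efficacy, starting from adults only: pure decay
  pv1 <- simulate_pupacide(p, pupacide_params(1, 1), 1e4,
                           lifecycle_state(M = 100), c(0, 60), dt_out = 5)
  expect_equal(pv1$states$M, 100 * exp(-p$mu_M * pv1$times),
               tolerance = 1e-6)
})

test_that("larviciding and pupaciding at half coverage are comparable", {
  p <- field_params()
  eq <- lifecycle_equilibrium(p, 1e4)
  base <- simulate_lifecycle(p, 1e4, eq, c(0, 1500), dt_out = 50)
  bti <- simulate_larvicide(p, larvicide_params(55.2, 0.5), 1e4, eq,
                            c(0, 1500), dt_out = 50)
  ppf <- simulate_pupacide(p, pupacide_params(0.95, 0.5), 1e4, eq,
                           c(0, 1500), dt_out = 50)
  r_bti <- percent_reduction(base, bti)
  r_ppf <- percent_reduction(base, ppf)
  expect_lt(abs(r_bti - r_ppf), 5)  # within a few percentage points
  expect_gt(r_bti, 20)              # and both are substantial
})

test_that("percent reduction handles the edge cases", {
  p <- field_params()
  eq <- lifecycle_equilibrium(p, 1e4)
  base <- simulate_lifecycle(p, 1e4, eq, c(0, 100), dt_out = 10)
  expect_equal(percent_reduction(base, base), 0)
  dead <- base
  dead$states$M <- rep(0, length(base$times))
  expect_equal(percent_reduction(base, dead), 100)
  expect_error(percent_reduction(dead, base), "zero")
})

test_that("the constant-emergence model obeys its closed form", {
  p <- field_params()
  sim <- simulate_constant_emergence(p, emergence_rate = 50,
                                     t_span = c(0, 200))
  expect_equal(sim$states$M, rep(50 / p$mu_M, length(sim$times)))
  # no emergence: exponential decay
  sim0 <- simulate_constant_emergence(p, 0, init_M = 80, t_span = c(0, 50))
  expect_equal(sim0$states$M, 80 * exp(-p$mu_M * sim0$times))
  # raising mu_M by factor f cuts the equilibrium by exactly 1 - 1/f
  f <- 2.5
  pf <- lifecycle_params(mu_M = p$mu_M * f)
  simf <- simulate_constant_emergence(pf, 50, t_span = c(0, 10))
  expect_equal(1 - tail(simf$states$M, 1) / tail(sim$states$M, 1),
               1 - 1 / f, tolerance = 1e-10)
})

test_that("egg inflow is conserved and split by coverage in treated models", {
  p <- field_params()
  covs <- c(0.2, 0.7)
  for (cv in covs) {
    eq <- lifecycle_equilibrium(p, 1e4)
    h <- 1e-3
    sim <- simulate_larvicide(p, larvicide_params(5, cv), 1e4, eq,
                              c(0, 2 * h), dt_out = h, rtol = 1e-10,
                              atol = 1e-12)
    # central finite difference at the midpoint state against the
    # expected egg inflow split (outflows subtracted analytically)
    s <- as.numeric(sim$states[2, ])
    names(s) <- names(sim$states)
    xu <- (s[["E"]] + s[["L"]]) / ((1 - cv) * 1e4)
    xt <- (s[["E_T"]] + s[["L_T"]]) / (cv * 1e4)
    dE <- (1 - cv) * p$beta * s[["M"]] - s[["E"]] / p$d_E -
      p$mu_E0 * (1 + xu) * s[["E"]]
    dET <- cv * p$beta * s[["M"]] - s[["E_T"]] / p$d_E -
      5 * p$mu_E0 * (1 + xt) * s[["E_T"]]
    scale <- p$beta * s[["M"]]
    expect_lt(abs((sim$states$E[3] - sim$states$E[1]) / (2 * h) - dE),
              1e-4 * scale)
    expect_lt(abs((sim$states$E_T[3] - sim$states$E_T[1]) / (2 * h) - dET),
              1e-4 * scale)
  }
})
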