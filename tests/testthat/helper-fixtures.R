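# shared fixtures built in code

# field-estimate parameter set used throughout the tests
field_params <- function() lifecycle_params()

# draw a full lifecycle parameter set (plus tau) from the priors
draw_prior_params <- function(priors = default_priors()) {
  nm <- c("d_E", "d_L", "d_P", "mu_E0", "mu_L0", "mu_P", "mu_M",
          "beta", "gamma")
  vals <- vapply(nm, function(n) gambiaedyn:::prior_sample(priors[[n]], 1),
                 numeric(1))
  suppressWarnings(do.call(lifecycle_params, as.list(vals)))
}

# small two-village synthetic study used by the inference tests
small_study <- function(seed = 7, lam = c(10, 25), r = 1) {
  sc <- synthetic_scenario(lam = lam, r = r, seed = seed)
  vs <- paste0("v", seq_along(lam))
  rainfall <- stats::setNames(lapply(seq_along(lam), function(i)
    generate_rainfall(sc, seed = seed + 1000L * i)), vs)
  catches <- generate_catches(sc, rainfall, villages = vs, seed = seed)
  list(scenario = sc, rainfall = rainfall, catches = catches)
}

# Jacobian of the lifecycle system at the extinction state (independent
# linearisation used as a growth-threshold oracle)
extinction_jacobian <- function(p) {
  matrix(c(
    -1 / p$d_E - p$mu_E0, 0, 0, p$beta,
    1 / p$d_E, -1 / p$d_L - p$mu_L0, 0, 0,
    0, 1 / p$d_L, -1 / p$d_P - p$mu_P, 0,
    0, 0, p$female_fraction / p$d_P, -p$mu_M
  ), nrow = 4, byrow = TRUE)
}
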