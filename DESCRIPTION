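Package: gambiaedyn
Title: Stage-Structured Population Dynamics of Anopheles gambiae with
    Rainfall-Driven Carrying Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the full Anopheles gambiae s.l. lifecycle (early
    instars, late instars, pupae, adult females) as a system of ordinary
    differential equations with linearly density-dependent larval
    mortality and an environmental carrying capacity driven by weighted
    recent rainfall. Provides the mosquito basic and effective
    reproduction-number calculus, models of vector control interventions
    (long-lasting insecticide-treated nets, indoor residual spraying,
    larviciding, pupaciding), Bayesian fitting of the model to nightly
    adult catch counts with a negative binomial observation model via
    adaptive random-walk Metropolis MCMC, and a generator of synthetic
    Sahelian rainfall and overdispersed catch data for testing and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
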