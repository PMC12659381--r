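# Independent numerical oracles used across test files.

# monthly death probability via adaptive quadrature of the hazard:
# q(tau) = 1 - exp(-int_tau^{tau+1} mu dt)
quadrature_death_prob <- function(model, tau) {
  vapply(tau, function(t0) {
    h <- stats::integrate(function(x) hazard_at(model, x),
                          lower = max(t0, 1e-12), upper = t0 + 1,
                          rel.tol = 1e-12, abs.tol = 1e-14)$value
    1 - exp(-h)
  }, numeric(1))
}

# central finite-difference hazard from the survival curve
finite_diff_hazard <- function(model, tau, h = 1e-5) {
  -(log(survival_at(model, tau + h)) - log(survival_at(model, tau - h))) /
    (2 * h)
}

# the four families with one representative parameterisation each
example_models <- function() {
  list(hazard_model("exponential", c(rate = 0.03)),
       hazard_model("weibull", c(shape = 0.8, scale = 60)),
       hazard_model("lognormal", c(meanlog = 3.2, sdlog = 1.1)),
       hazard_model("loglogistic", c(alpha = 36, beta = 1.5)))
}

# a minimal bundle with one chronic disease, used for targeted engine tests
one_disease_bundle <- function(rate_t = 0.002, rate_u = 0.05,
                               incidence = 50, annual = 600,
                               war_start = 36L, tau_max = 120L) {
  grid <- time_grid(war_start = war_start, tau_max = tau_max)
  shares <- stats::setNames(rep(1 / 9, 9),
                            c("0-9", "10-19", "20-29", "30-39", "40-49",
                              "50-59", "60-69", "70-79", "80+"))
  d <- disease_spec(
    id = "chronic_a", kind = "chronic",
    hazards = list(
      treated = hazard_model("exponential", c(rate = rate_t), "treated"),
      untreated = hazard_model("exponential", c(rate = rate_u))),
    baseline_years = 2000:2002, baseline_deaths = rep(annual, 3),
    age_shares = shares, mean_incidence = incidence)
  cov <- coverage_schedule(do.call(rbind, c(
    list(data.frame(disease = "chronic_a", period = "baseline",
                    scenario = "baseline", lo = 0.90, hi = 1.00)),
    lapply(projection_scenarios(), function(sc)
      data.frame(disease = "chronic_a",
                 period = c("to_date", "proj_m1_3", "proj_m4_6"),
                 scenario = sc,
                 lo = c(0.3, 0.3, 0.3) - 0.1 * (match(sc, projection_scenarios()) - 1),
                 hi = c(0.6, 0.6, 0.6) - 0.1 * (match(sc, projection_scenarios()) - 1))))))
  pop <- data.frame(stratum = names(shares), count = rep(1e5, 9))
  scenario_bundle(list(d), cov, pop, grid, n_runs = 100L, seed = 7L)
}

published_table <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "ncdexcess"),
                  stringsAsFactors = FALSE)
}
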