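test_that("closed-form hazards evaluate to their known values", {
  expect_equal(hazard_at(hazard_model("exponential", c(rate = 0.02)), 7),
               0.02)
  # standard log-normal at tau = 1 with meanlog 0, sdlog 1:
  # phi(0) / (1 - Phi(0)) = 0.3989423 / 0.5
  expect_equal(
    hazard_at(hazard_model("lognormal", c(meanlog = 0, sdlog = 1)), 1),
    dnorm(0) / pnorm(0, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(
    round(hazard_at(hazard_model("lognormal", c(meanlog = 0, sdlog = 1)), 1),
          5), 0.79788)
  expect_equal(
    hazard_at(hazard_model("loglogistic", c(alpha = 10, beta = 1)), 10),
    0.05)
})

test_that("survival curves are proper and consistent with the hazard", {
  expect_equal(
    survival_at(hazard_model("exponential", c(rate = 0.05)), 12),
    exp(-0.6))
  for (m in example_models()) {
    expect_identical(survival_at(m, 0), 1)
    s <- survival_at(m, seq(0, 240, by = 1))
    expect_true(all(diff(s) <= 0))
    expect_true(all(s > 0 & s <= 1))
    # mu(tau) = -d ln S / d tau, checked by central differences
    for (tau in c(6, 24, 90))
      expect_equal(finite_diff_hazard(m, tau), hazard_at(m, tau),
                   tolerance = 1e-6)
  }
})

test_that("discrete monthly death probability matches hazard quadrature", {
  m <- hazard_model("exponential", c(rate = 0.05))
  expect_equal(discrete_death_prob(m, c(0, 3, 40)),
               rep(1 - exp(-0.05), 3))
  expect_equal(discrete_death_prob(
    hazard_model("exponential", c(rate = 0)), 5), 0)
  for (m in example_models())
    for (tau in c(0, 1, 12, 120))
      expect_equal(discrete_death_prob(m, tau),
                   quadrature_death_prob(m, tau), tolerance = 1e-8)
})

test_that("Weibull with shape 1 degenerates to the exponential", {
  w <- hazard_model("weibull", c(shape = 1, scale = 25))
  e <- hazard_model("exponential", c(rate = 1 / 25))
  tau <- c(0.5, 1, 7, 60, 200)
  expect_equal(hazard_at(w, tau), hazard_at(e, tau), tolerance = 1e-12)
  expect_equal(survival_at(w, tau), survival_at(e, tau), tolerance = 1e-12)
})

test_that("unit conversion rescales each family correctly and is idempotent", {
  e <- hazard_model("exponential", c(rate = 0.12), unit = "year")
  e_m <- convert_hazard_units(e)
  expect_equal(unname(e_m$params["rate"]), 0.01)
  expect_identical(convert_hazard_units(e_m), e_m)

  # survival is invariant: S_year(tau years) = S_month(12 tau months)
  yearly <- list(
    hazard_model("exponential", c(rate = 0.2), unit = "year"),
    hazard_model("weibull", c(shape = 1.3, scale = 8), unit = "year"),
    hazard_model("lognormal", c(meanlog = 1.5, sdlog = 0.9), unit = "year"),
    hazard_model("loglogistic", c(alpha = 5, beta = 2), unit = "year"))
  for (m in yearly) {
    mm <- convert_hazard_units(m)
    for (t_yr in c(0.5, 1, 4, 10)) {
      m_native <- m; m_native$unit <- "month"   # evaluate formula as-is
      expect_equal(survival_at(mm, 12 * t_yr), survival_at(m_native, t_yr),
                   tolerance = 1e-12)
    }
  }
  m_bad <- hazard_model("exponential", c(rate = 1), unit = "fortnight")
  expect_error(convert_hazard_units(m_bad), "unit")
})

test_that("domain and parameter validation reject bad input", {
  m <- hazard_model("exponential", c(rate = 0.05))
  expect_error(hazard_at(m, 0), "tau")
  expect_error(hazard_at(m, -3), "tau")
  expect_error(survival_at(m, -1), "tau")
  expect_error(hazard_model("weibull", c(shape = -1, scale = 10)),
               "invalid parameters")
  expect_error(hazard_model("lognormal", c(meanlog = 0, sdlog = 0)),
               "invalid parameters")
  expect_error(hazard_model("exponential", c(lambda = 0.1)), "needs")
})

test_that("acute-event conditioning rescales survival and guards bounds", {
  obs <- survival_obs(c(6, 12, 24), c(0.60, 0.45, 0.30), n_eff = 500)
  expect_equal(condition_on_acute_survival(obs, 0)$surviving,
               obs$surviving)
  cond <- condition_on_acute_survival(obs, 0.10)
  expect_equal(cond$surviving[2], 0.5)
  expect_true(all(diff(cond$surviving) <= 0))
  obs_hi <- survival_obs(6, 0.95)
  expect_error(condition_on_acute_survival(obs_hi, 0.10), "exceeds")
  expect_error(condition_on_acute_survival(obs, 1), "mu_acute")
})
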