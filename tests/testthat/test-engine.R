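make_grid <- function(war_start = 120L, tau_max = 240L)
  time_grid(war_start = war_start, tau_max = tau_max)

test_that("coverage sampling respects its uniform range", {
  sched <- coverage_schedule(data.frame(
    disease = "d", period = "baseline", scenario = "baseline",
    lo = c(0.95, 0.90)[1], hi = c(0.95, 1.00)[1]))
  expect_equal(sample_coverage(sched, "d", "baseline", "baseline"), 0.95)

  sched2 <- coverage_schedule(data.frame(
    disease = "d", period = "baseline", scenario = "baseline",
    lo = 0.90, hi = 1.00))
  set.seed(1)
  draws <- replicate(10000, sample_coverage(sched2, "d", "baseline",
                                            "baseline"))
  expect_true(all(draws >= 0.90 & draws <= 1.00))
  expect_equal(mean(draws), 0.95, tolerance = 0.003 / 0.95)
  expect_error(sample_coverage(sched2, "d", "to_date", "ceasefire"),
               "no coverage range")
})

test_that("hazard-bound mixing is linear with the documented endpoints", {
  lo <- hazard_model("exponential", c(rate = 0.01), bound = "lower")
  hi <- hazard_model("exponential", c(rate = 0.04), bound = "upper")
  pair <- list(lower = lo, upper = hi)

  single <- sample_hazard(lo)
  expect_equal(single(c(0, 5, 12)), discrete_death_prob(lo, c(0, 5, 12)))
  expect_equal(sample_hazard(pair, w = 0)(12),
               discrete_death_prob(hi, 12))
  expect_equal(sample_hazard(pair, w = 1)(12),
               discrete_death_prob(lo, 12))
  set.seed(2)
  ws <- runif(10000)
  qs <- vapply(ws, function(w) sample_hazard(pair, w = w)(12), numeric(1))
  mid <- mean(c(discrete_death_prob(lo, 12), discrete_death_prob(hi, 12)))
  expect_equal(mean(qs), mid, tolerance = 3 * sd(qs) / sqrt(10000) / mid)
})

test_that("chronic ledger reaches renewal equilibrium: deaths equal incidence", {
  # with untreated-only exponential mortality and constant incidence, every
  # case eventually dies, so post-burn-in monthly deaths equal incidence
  grid <- make_grid()
  spec <- one_disease_bundle()$diseases[[1]]
  spec$calibration_k <- 1
  lambda <- 0.1
  q_u <- 1 - exp(-lambda)
  deaths <- simulate_chronic(spec, rep(0, grid$n_months), q_T = 0,
                             q_U = q_u, grid, mode = "expectation",
                             incident = rep(50, grid$n_months))
  expect_equal(deaths[grid$n_months], 50, tolerance = 1e-3)

  # full protection: no deaths at all
  none <- simulate_chronic(spec, rep(1, grid$n_months), q_T = 0,
                           q_U = q_u, grid, mode = "expectation",
                           incident = rep(50, grid$n_months))
  expect_equal(none, rep(0, grid$n_months))
})

test_that("stochastic ledger agrees with expectation mode on average", {
  grid <- time_grid(war_start = 24L, tau_max = 60L)
  spec <- one_disease_bundle()$diseases[[1]]
  spec$calibration_k <- 1
  spec$mean_incidence <- 40   # same mean drives both modes
  path <- rep(0.5, grid$n_months)
  q_T <- discrete_death_prob(hazard_model("exponential", c(rate = 0.005)),
                             0:(grid$tau_max - 1))
  q_U <- discrete_death_prob(hazard_model("exponential", c(rate = 0.06)),
                             0:(grid$tau_max - 1))
  exp_deaths <- simulate_chronic(spec, path, q_T, q_U, grid,
                                 mode = "expectation",
                                 incident = rep(40, grid$n_months))
  set.seed(99)
  n_rep <- 200
  sims <- replicate(n_rep, simulate_chronic(
    spec, path, q_T, q_U, grid, mode = "stochastic"))
  mc_mean <- rowMeans(sims)
  mc_se <- apply(sims, 1, sd) / sqrt(n_rep)
  late <- (grid$war_start + 1):grid$n_months
  expect_true(all(abs(mc_mean[late] - exp_deaths[late]) <=
                    3 * mc_se[late] + 1e-9))
})

test_that("acute CVD branch reduces to and extends the chronic ledger", {
  grid <- time_grid(war_start = 24L, tau_max = 60L)
  spec <- one_disease_bundle()$diseases[[1]]
  spec$calibration_k <- 1
  spec$kind <- "cvd_acute"
  q_T <- 0.001; q_U <- 0.05
  path <- rep(0.8, grid$n_months)
  inc <- rep(100, grid$n_months)

  spec0 <- spec; spec0$acute <- acute_risk(0, 0)
  expect_equal(
    simulate_cvd(spec0, path, q_T, q_U, grid, mode = "expectation",
                 incident = inc),
    simulate_chronic(spec, path, q_T, q_U, grid, mode = "expectation",
                     incident = inc))

  # c = 1, mu_acute_T = 0.2: 20 acute deaths, 80 survivors enter the
  # chronic cohort in the onset month
  spec2 <- spec; spec2$acute <- acute_risk(0.2, 0.5)
  d <- simulate_cvd(spec2, rep(1, grid$n_months), q_T = 0.01, q_U = 0.5,
                    grid, mode = "expectation", incident = inc)
  expect_equal(d[1], 100 * 0.2 + 80 * 0.01, tolerance = 1e-12)

  # mixture mean: c = 0.5 of 0.1 and 0.3 gives 20% acute mortality
  spec3 <- spec; spec3$acute <- acute_risk(0.1, 0.3)
  d3 <- simulate_cvd(spec3, rep(0.5, grid$n_months), q_T = 0, q_U = 0,
                     grid, mode = "expectation", incident = inc)
  expect_equal(d3, rep(20, grid$n_months))

  spec_na <- spec; spec_na$acute <- NULL
  expect_error(simulate_cvd(spec_na, path, q_T, q_U, grid,
                            mode = "expectation", incident = inc),
               "acute")
})

test_that("prevalent pool depletes from crisis onset with no new entrants", {
  grid <- time_grid(war_start = 10L, tau_max = 10L)
  spec <- disease_spec(
    id = "pool", kind = "prevalent_pool",
    hazards = list(
      treated = hazard_model("exponential", c(rate = 0), "treated"),
      untreated = hazard_model("exponential", c(rate = 0.05))),
    age_shares = setNames(rep(1 / 9, 9), paste0("s", 1:9)),
    prevalent_pool_size = 1000)

  silent <- simulate_prevalent_pool(spec, rep(1, grid$n_months),
                                    q_T = 0, q_U = 0.05, grid,
                                    mode = "expectation")
  expect_equal(silent, rep(0, grid$n_months))

  d <- simulate_prevalent_pool(spec, rep(0, grid$n_months),
                               q_T = 0, q_U = 0.05, grid,
                               mode = "expectation")
  expect_equal(d[1:10], rep(0, 10))          # nothing before onset
  expect_equal(d[11], 50)                    # 1000 x 0.05
  expect_equal(sum(d[11:12]), 1000 * (1 - 0.95^2))  # 97.5 cumulative
})

test_that("calibration scales incidence linearly onto the forecast target", {
  b <- one_disease_bundle(annual = 600)
  b <- calibrate_bundle(b)
  d <- b$diseases[[1]]
  expect_gt(d$calibration_k, 0)
  # re-simulating the counterfactual at the calibrated incidence hits the
  # forecast in the reference window (expectation mode: exact up to the
  # linearity of the ledger in incidence)
  g <- b$grid
  window <- (g$war_start - 11L):g$war_start
  q_T <- ncdexcess:::death_prob_vector(d$hazards$treated, g$tau_max)
  q_U <- ncdexcess:::death_prob_vector(d$hazards$untreated, g$tau_max)
  path <- rep(0.95, g$n_months)
  sim <- simulate_chronic(d, path, q_T, q_U, g, mode = "expectation")
  expect_equal(mean(sim[window]), mean(d$baseline_monthly[window]),
               tolerance = 1e-9)
  # halving the hazard target halves k
  b2 <- one_disease_bundle(annual = 300)
  b2 <- calibrate_bundle(b2)
  expect_equal(b2$diseases[[1]]$calibration_k, d$calibration_k / 2,
               tolerance = 1e-9)

  spec0 <- b$diseases[[1]]
  expect_warning(
    k0 <- calibrate_incidence(spec0, numeric(g$n_months), b$coverage, g),
    "k = 0")
  expect_identical(k0, 0)
})

test_that("deaths never exceed incidence and respond monotonically to coverage", {
  grid <- time_grid(war_start = 24L, tau_max = 48L)
  spec <- one_disease_bundle()$diseases[[1]]
  spec$calibration_k <- 1
  q_T <- discrete_death_prob(hazard_model("exponential", c(rate = 0.002)),
                             0:(grid$tau_max - 1))
  q_U <- discrete_death_prob(hazard_model("exponential", c(rate = 0.08)),
                             0:(grid$tau_max - 1))
  inc <- rep(30, grid$n_months)
  for (mode in c("expectation", "stochastic")) {
    set.seed(3)
    d <- simulate_chronic(spec, rep(0.7, grid$n_months), q_T, q_U, grid,
                          mode = mode, incident = inc)
    expect_true(all(cumsum(d) <= cumsum(inc) + 1e-9))
  }
  hi_cov <- simulate_chronic(spec, rep(0.9, grid$n_months), q_T, q_U,
                             grid, mode = "expectation", incident = inc)
  lo_cov <- simulate_chronic(spec, rep(0.4, grid$n_months), q_T, q_U,
                             grid, mode = "expectation", incident = inc)
  expect_true(all(lo_cov >= hi_cov - 1e-12))
})

test_that("aggregate simulation equals summed per-stratum simulation", {
  # with age-independent hazards and coverage the ledger is linear in
  # incidence, so simulating the total and allocating by age equals
  # simulating each stratum at incidence I * p_a
  grid <- time_grid(war_start = 24L, tau_max = 48L)
  spec <- one_disease_bundle()$diseases[[1]]
  spec$calibration_k <- 1
  shares <- c(0.2, 0.3, 0.5)
  path <- rep(0.6, grid$n_months)
  q_T <- 0.002; q_U <- 0.05
  inc_tot <- rep(60, grid$n_months)
  total <- simulate_chronic(spec, path, q_T, q_U, grid,
                            mode = "expectation", incident = inc_tot)
  by_stratum <- sapply(shares, function(p)
    simulate_chronic(spec, path, q_T, q_U, grid, mode = "expectation",
                     incident = inc_tot * p))
  expect_equal(rowSums(by_stratum), total, tolerance = 1e-9)
  expect_equal(allocate_by_age(total, setNames(shares, c("a", "b", "c"))),
               t(apply(by_stratum, 1, function(r)
                 setNames(r, c("a", "b", "c")))), tolerance = 1e-9)
})

test_that("expectation-mode ledger matches the convolution oracle exactly", {
  grid <- time_grid(war_start = 24L, tau_max = 48L)
  spec <- one_disease_bundle()$diseases[[1]]
  spec$calibration_k <- 1
  path <- c(rep(0.95, 24), rep(0.35, grid$n_months - 24))
  q_T <- discrete_death_prob(hazard_model("weibull",
                                          c(shape = 0.8, scale = 90)),
                             0:(grid$tau_max - 1))
  q_U <- discrete_death_prob(hazard_model("exponential", c(rate = 0.07)),
                             0:(grid$tau_max - 1))
  inc <- rep(25, grid$n_months)
  engine <- simulate_chronic(spec, path, q_T, q_U, grid,
                             mode = "expectation", incident = inc)
  oracle <- oracle_expected_deaths(25, q_T, q_U, path, grid$tau_max)
  expect_equal(engine, oracle, tolerance = 1e-12)
})
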