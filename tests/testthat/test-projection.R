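test_that("paired runs with crisis coverage at baseline give exactly zero excess", {
  g <- generate_inputs(seed = 8, profile = "small", oracle = FALSE)
  b <- g$bundle
  cov <- as.data.frame(b$coverage)
  cov$lo <- 0.90; cov$hi <- 1.00
  b$coverage <- coverage_schedule(cov)
  led <- run_projection(b, "escalation", n_runs = 50)
  worst <- max(vapply(led, function(l) max(abs(l$excess)), numeric(1)))
  expect_identical(worst, 0)
  # all three structural kinds are present in the bundle
  expect_setequal(unname(vapply(b$diseases, `[[`, "", "kind")),
                  c("cvd_acute", "chronic", "prevalent_pool"))
})

test_that("identical bundle and seed reproduce bit-identical ledgers", {
  b <- generate_inputs(seed = 9, profile = "small", oracle = FALSE)$bundle
  l1 <- run_projection(b, "ceasefire", n_runs = 5)
  l2 <- run_projection(b, "ceasefire", n_runs = 5)
  expect_identical(l1, l2)
  l3 <- run_projection(b, "ceasefire", n_runs = 5, seed = 123)
  expect_false(identical(l1, l3))
})

test_that("nested coverage ranges order the scenarios' expected excess", {
  b <- generate_inputs(seed = 10, profile = "small", oracle = FALSE)$bundle
  totals <- vapply(projection_scenarios(), function(sc) {
    led <- run_projection(b, sc, mode = "expectation")
    sum(led[[1]]$excess)
  }, numeric(1))
  expect_true(totals["ceasefire"] <= totals["status_quo"])
  expect_true(totals["status_quo"] <= totals["escalation"])
})

test_that("summaries have exact degenerate and known-quantile behaviour", {
  b <- generate_inputs(seed = 11, profile = "small", oracle = FALSE)$bundle
  b <- calibrate_bundle(b)
  age_dists <- lapply(b$diseases, `[[`, "age_shares")

  led1 <- run_projection(b, "status_quo", n_runs = 1)
  s1 <- summarise_runs(led1, b$grid, age_dists)
  expect_equal(s1$by_disease$pi_lo, s1$by_disease$mean)
  expect_equal(s1$by_disease$pi_hi, s1$by_disease$mean)

  # inject standard-normal per-run totals through hand-built ledgers
  set.seed(12)
  x <- rnorm(10000)
  m1 <- ncdexcess:::period_months(b$grid, "proj_m1_3")[1] + 1L
  fake <- lapply(x, function(v) {
    z <- matrix(0, b$grid$n_months, 1, dimnames = list(NULL, "d"))
    cr <- z; cr[m1, 1] <- v
    structure(list(run = 1, crisis = cr, counterfactual = z,
                   excess = cr), class = "run_ledger")
  })
  sf <- summarise_runs(fake, b$grid,
                       list(d = c(young = 0.5, old = 0.5)),
                       scenario = "test")
  tot <- sf$by_disease[sf$by_disease$disease == "d" &
                         sf$by_disease$sub_period == "total", ]
  expect_equal(tot$pi_lo, -1.96, tolerance = 0.05 / 1.96)
  expect_equal(tot$pi_hi, 1.96, tolerance = 0.05 / 1.96)

  # sub-period means sum to the total row
  s20 <- summarise_runs(run_projection(b, "status_quo", n_runs = 20),
                        b$grid, age_dists)
  bd <- s20$by_disease
  for (d in unique(bd$disease)) {
    parts <- bd$mean[bd$disease == d & bd$sub_period != "total"]
    total <- bd$mean[bd$disease == d & bd$sub_period == "total"]
    expect_equal(sum(parts), total, tolerance = 1e-6)
  }
  # age-row totals agree with the disease total
  ba <- s20$by_age
  expect_equal(sum(ba$mean[ba$sub_period == "total"]),
               bd$mean[bd$disease == "all" & bd$sub_period == "total"],
               tolerance = 1e-6)
})

test_that("excess is translation-consistent in the two arms", {
  b <- generate_inputs(seed = 13, profile = "small", oracle = FALSE)$bundle
  b <- calibrate_bundle(b)
  led <- run_projection(b, "ceasefire", n_runs = 3)
  shifted <- lapply(led, function(l) {
    l$crisis <- l$crisis + 11
    l$counterfactual <- l$counterfactual + 11
    l$excess <- l$crisis - l$counterfactual
    l
  })
  attributes(shifted) <- attributes(led)
  age_dists <- lapply(b$diseases, `[[`, "age_shares")
  s0 <- summarise_runs(led, b$grid, age_dists)
  s1 <- summarise_runs(shifted, b$grid, age_dists)
  expect_equal(s1$by_disease$mean, s0$by_disease$mean, tolerance = 1e-9)
  expect_equal(s1$by_age, s0$by_age, tolerance = 1e-9)
})

test_that("age_share aggregates mean excess above a threshold stratum", {
  tab <- data.frame(stratum = c("0-49", "50-59", "60+"),
                    mean = c(10, 30, 60))
  expect_identical(age_share(tab, "50-59"), 90L)
  degen <- data.frame(stratum = c("0-79", "80+"), mean = c(0, 42))
  expect_identical(age_share(degen, "80+"), 100L)
  expect_error(age_share(tab, "90+"), "missing stratum")
})

test_that("the top-level projection object carries methods and calibration", {
  g <- generate_inputs(seed = 14, profile = "small", oracle = FALSE)
  proj <- project_excess(g$bundle, scenarios = "status_quo", n_runs = 10)
  expect_s3_class(proj, "ncd_projection")
  ks <- coef(proj)
  expect_true(all(ks[names(ks) != "dm1"] > 0))
  expect_output(print(proj), "status_quo")
  s <- summary(proj)
  expect_s3_class(s, "excess_summary")
  expect_true(all(c("by_disease", "by_age", "monthly") %in% names(s)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(proj))
})
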