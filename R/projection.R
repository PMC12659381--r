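#' Calibrate every disease in a bundle to its counterfactual baseline
#'
#' Fits the Poisson year-trend to each disease's pre-crisis annual death
#' series, discretises the forecast to months, and sets the incidence
#' calibration multiplier \eqn{k} so expected counterfactual deaths over
#' the final pre-crisis year match the forecast. Prevalent-pool diseases
#' (type-1 diabetes) are skipped: their baseline mortality is zero by
#' assumption.
#'
#' @param bundle a \code{\link{scenario_bundle}}.
#' @return the bundle with \code{calibration_k} and a monthly baseline
#'   forecast (\code{baseline_monthly}) filled in on every disease.
#' @export
calibrate_bundle <- function(bundle) {
  g <- bundle$grid
  for (id in names(bundle$diseases)) {
    d <- bundle$diseases[[id]]
    if (d$kind == "prevalent_pool") {
      d$baseline_monthly <- numeric(g$n_months)
      d$calibration_k <- 0
    } else {
      trend <- fit_baseline_trend(d$baseline_years, d$baseline_deaths)
      d$baseline_monthly <- forecast_monthly_baseline(trend, g)
      d$trend <- trend
      d$calibration_k <- calibrate_incidence(d, d$baseline_monthly,
                                             bundle$coverage, g)
    }
    bundle$diseases[[id]] <- d
  }
  bundle
}

# per-run shared randomness: coverage quantiles, bound-mixing weight,
# incident draws and the per-arm death-draw seed (common random numbers)
draw_run_randomness <- function(bundle, mode) {
  g <- bundle$grid
  periods <- c("baseline", analysis_periods())
  lapply(bundle$diseases, function(d) {
    if (mode == "expectation") {
      u <- stats::setNames(rep(0.5, length(periods)), periods)
      w <- 0.5
      arm_seed <- NA_integer_
      incident <- if (d$kind == "prevalent_pool") NULL
      else rep((d$calibration_k %||% 1) * d$mean_incidence, g$n_months)
    } else {
      u <- stats::setNames(stats::runif(length(periods)), periods)
      w <- stats::runif(1)
      arm_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      incident <- if (d$kind == "prevalent_pool") NULL
      else stats::rpois(g$n_months, d$calibration_k * d$mean_incidence)
    }
    list(u = u, w = w, arm_seed = arm_seed, incident = incident)
  })
}

# coverage path over the grid for one arm: burn-in months use the baseline
# range; analysis-period months use the arm's range for that period, mapped
# through the shared quantile
build_coverage_path <- function(bundle, disease, scenario, u, arm) {
  g <- bundle$grid
  path <- numeric(g$n_months)
  path[g$period == "burn_in"] <-
    sample_coverage(bundle$coverage, disease, "baseline", "baseline",
                    u = u[["baseline"]])
  for (p in analysis_periods()) {
    cvg <- if (arm == "counterfactual")
      sample_coverage(bundle$coverage, disease, "baseline", "baseline",
                      u = u[[p]])
    else
      sample_coverage(bundle$coverage, disease, p, scenario, u = u[[p]])
    path[g$period == p] <- cvg
  }
  path
}

simulate_disease_arm <- function(d, path, grid, mode, incident, w,
                                 crisis = FALSE) {
  phi_cfr <- if (crisis) d$phi_cfr else 1
  phi_inc <- if (crisis) d$phi_incidence else 1
  q_T <- death_prob_vector(d$hazards$treated, grid$tau_max, w = w,
                           cfr_multiplier = phi_cfr)
  q_U <- death_prob_vector(d$hazards$untreated, grid$tau_max, w = w,
                           cfr_multiplier = phi_cfr)
  switch(d$kind,
    chronic = simulate_chronic(d, path, q_T, q_U, grid, mode = mode,
                               incident = incident * phi_inc),
    cvd_acute = simulate_cvd(d, path, q_T, q_U, grid, mode = mode,
                             incident = incident * phi_inc,
                             cfr_multiplier = phi_cfr),
    prevalent_pool = simulate_prevalent_pool(d, path, q_T, q_U, grid,
                                             mode = mode))
}

#' Run paired crisis/counterfactual simulations for one scenario
#'
#' Each run simulates every disease twice under common random numbers: the
#' crisis arm uses the scenario's period coverage ranges, the
#' counterfactual arm the pre-crisis baseline range throughout; both arms
#' share the incident-case draws, the survival bound-mixing weight, the
#' per-period coverage quantiles (each arm maps the quantile through its
#' own range) and the binomial death-draw stream. Per-run excess is the
#' month-by-month difference in deaths, so when crisis ranges equal
#' baseline ranges the excess is exactly zero.
#'
#' @param bundle a calibrated \code{\link{scenario_bundle}} (see
#'   \code{\link{calibrate_bundle}}; calibration is triggered here if
#'   absent).
#' @param scenario one of \code{\link{projection_scenarios}}.
#' @param mode \code{"stochastic"} (default) or \code{"expectation"}
#'   (deterministic single run at the mean of every draw).
#' @param n_runs number of Monte-Carlo runs; defaults to
#'   \code{bundle$n_runs}; forced to 1 in expectation mode.
#' @param seed integer seed for this scenario's run stream; defaults to a
#'   scenario-specific offset of \code{bundle$seed}.
#' @return list of class \code{run_ledger_list}: one ledger per run, each
#'   with matrices \code{crisis}, \code{counterfactual}, \code{excess}
#'   (months x diseases) and the sampled coverage quantiles and weights.
#' @export
run_projection <- function(bundle, scenario,
                           mode = c("stochastic", "expectation"),
                           n_runs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!scenario %in% projection_scenarios())
    stop_config("unknown scenario '", scenario, "'; valid scenarios: ",
                paste(projection_scenarios(), collapse = ", "))
  if (any(vapply(bundle$diseases,
                 function(d) is.na(d$calibration_k), logical(1))))
    bundle <- calibrate_bundle(bundle)
  g <- bundle$grid
  n_runs <- if (mode == "expectation") 1L
  else as.integer(n_runs %||% bundle$n_runs)
  if (is.null(seed))
    seed <- (bundle$seed + 97L * match(scenario, projection_scenarios())) %%
      (.Machine$integer.max - 1L)

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  ids <- names(bundle$diseases)

  ledgers <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    shared <- draw_run_randomness(bundle, mode)
    crisis <- counter <- matrix(0, g$n_months, length(ids),
                                dimnames = list(NULL, ids))
    for (id in ids) {
      d <- bundle$diseases[[id]]
      s <- shared[[id]]
      path_cr <- build_coverage_path(bundle, id, scenario, s$u, "crisis")
      path_cf <- build_coverage_path(bundle, id, scenario, s$u,
                                     "counterfactual")
      if (mode == "stochastic") set.seed(s$arm_seed)
      crisis[, id] <- simulate_disease_arm(d, path_cr, g, mode,
                                           s$incident, s$w, crisis = TRUE)
      if (mode == "stochastic") set.seed(s$arm_seed)
      counter[, id] <- simulate_disease_arm(d, path_cf, g, mode,
                                            s$incident, s$w)
    }
    ledgers[[r]] <- structure(
      list(run = r, crisis = crisis, counterfactual = counter,
           excess = crisis - counter,
           coverage_quantiles = lapply(shared, `[[`, "u"),
           bound_weights = vapply(shared, `[[`, numeric(1), "w")),
      class = "run_ledger")
  }
  structure(ledgers, class = "run_ledger_list",
            scenario = scenario, mode = mode, seed = seed)
}

#' Summarise run ledgers into the reporting tables
#'
#' Computes, per disease and analysis sub-period, the mean and empirical
#' 2.5th/97.5th percentiles (linear interpolation) across runs of summed
#' excess deaths, along with mean crisis and counterfactual deaths; an
#' all-disease total; per-age-stratum rows obtained by allocating each
#' disease's per-run excess through its age distribution before taking
#' percentiles; and mean monthly trajectories from crisis onset. Negative
#' per-run excess is retained, never truncated.
#'
#' @param ledgers a \code{run_ledger_list} from
#'   \code{\link{run_projection}}.
#' @param grid the bundle's \code{\link{time_grid}}.
#' @param age_dists named list (by disease) of age-share vectors.
#' @param scenario label stamped on the output rows.
#' @return object of class \code{excess_summary}: list of data.frames
#'   \code{by_disease}, \code{by_age}, \code{monthly}.
#' @export
summarise_runs <- function(ledgers, grid, age_dists,
                           scenario = attr(ledgers, "scenario")) {
  stopifnot(length(ledgers) >= 1)
  ids <- colnames(ledgers[[1]]$excess)
  periods <- analysis_periods()
  n_runs <- length(ledgers)

  # per-run sums: runs x diseases x periods
  per_run <- vapply(ledgers, function(l) {
    vapply(periods, function(p) {
      m <- period_months(grid, p) + 1L
      colSums(l$excess[m, , drop = FALSE])
    }, numeric(length(ids)))
  }, matrix(0, length(ids), length(periods)))
  per_run <- array(per_run, c(length(ids), length(periods), n_runs),
                   dimnames = list(ids, periods, NULL))
  crisis_run <- vapply(ledgers, function(l) {
    vapply(periods, function(p) {
      m <- period_months(grid, p) + 1L
      colSums(l$crisis[m, , drop = FALSE])
    }, numeric(length(ids)))
  }, matrix(0, length(ids), length(periods)))
  crisis_run <- array(crisis_run, dim(per_run), dimnames = dimnames(per_run))
  counter_run <- crisis_run - per_run

  summarise_cell <- function(x)   # x: vector over runs
    c(mean = mean(x),
      pi_lo = unname(stats::quantile(x, 0.025)),
      pi_hi = unname(stats::quantile(x, 0.975)))

  rows <- list()
  add_row <- function(disease, sub_period, stratum, excess_runs,
                      crisis_runs = NA, counter_runs = NA) {
    s <- summarise_cell(excess_runs)
    rows[[length(rows) + 1L]] <<- data.frame(
      disease = disease, scenario = scenario, sub_period = sub_period,
      stratum = stratum, mean = s["mean"], pi_lo = s["pi_lo"],
      pi_hi = s["pi_hi"],
      mean_crisis = if (all(is.na(crisis_runs))) NA else mean(crisis_runs),
      mean_counterfactual = if (all(is.na(counter_runs))) NA
      else mean(counter_runs),
      row.names = NULL)
  }

  over_runs <- function(a, id = NULL, p = NULL) {  # sum cells, keep runs
    if (!is.null(id)) a <- a[id, , , drop = FALSE]
    if (!is.null(p)) a <- a[, p, , drop = FALSE]
    apply(a, 3, sum)
  }
  for (id in ids) {
    for (p in periods)
      add_row(id, p, "all", over_runs(per_run, id, p),
              over_runs(crisis_run, id, p), over_runs(counter_run, id, p))
    add_row(id, "total", "all", over_runs(per_run, id),
            over_runs(crisis_run, id), over_runs(counter_run, id))
  }
  for (p in periods)
    add_row("all", p, "all", over_runs(per_run, p = p),
            over_runs(crisis_run, p = p), over_runs(counter_run, p = p))
  add_row("all", "total", "all", over_runs(per_run),
          over_runs(crisis_run), over_runs(counter_run))
  by_disease <- do.call(rbind, rows)

  # age rows: allocate each disease's per-run excess by its age shares,
  # sum across diseases, then summarise across runs
  strata <- names(age_dists[[ids[1]]])
  rows <- list()
  for (p in c(periods, "total")) {
    ex_runs <- if (p == "total") apply(per_run, c(1, 3), sum)
    else apply(per_run[, p, , drop = FALSE], c(1, 3), sum)
    ex_runs <- matrix(ex_runs, nrow = length(ids),
                      dimnames = list(ids, NULL))
    by_stratum <- matrix(0, length(strata), n_runs,
                         dimnames = list(strata, NULL))
    for (id in ids)
      by_stratum <- by_stratum + outer(age_dists[[id]][strata],
                                       ex_runs[id, ])
    for (st in strata) {
      s <- summarise_cell(by_stratum[st, ])
      rows[[length(rows) + 1L]] <- data.frame(
        disease = "all", scenario = scenario, sub_period = p,
        stratum = st, mean = s["mean"], pi_lo = s["pi_lo"],
        pi_hi = s["pi_hi"], row.names = NULL)
    }
  }
  by_age <- do.call(rbind, rows)

  months <- grid$war_start:(grid$n_months - 1L)
  monthly <- data.frame(
    month = months, scenario = scenario,
    period = grid$period[months + 1L],
    crisis = rowMeans(vapply(ledgers, function(l)
      rowSums(l$crisis[months + 1L, , drop = FALSE]), numeric(length(months)))),
    counterfactual = rowMeans(vapply(ledgers, function(l)
      rowSums(l$counterfactual[months + 1L, , drop = FALSE]),
      numeric(length(months)))))
  monthly$excess <- monthly$crisis - monthly$counterfactual

  structure(list(by_disease = by_disease, by_age = by_age,
                 monthly = monthly),
            class = "excess_summary")
}

#' @export
print.excess_summary <- function(x, ...) {
  cat("Excess-mortality summary (", nrow(x$by_disease), "disease rows,",
      nrow(x$by_age), "age rows )\n")
  tot <- x$by_disease[x$by_disease$disease == "all" &
                        x$by_disease$sub_period == "total", ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  %s: %s excess deaths (95%% PI %s to %s)\n",
                tot$scenario[i], format_count(tot$mean[i]),
                format_count(tot$pi_lo[i]), format_count(tot$pi_hi[i])))
  invisible(x)
}

#' Share of excess deaths at or above an age stratum
#'
#' Sums mean excess deaths over the strata at and above a threshold
#' stratum and divides by the all-strata sum, reported as a percentage
#' rounded to the nearest integer. Strata are taken in their order of
#' appearance (youngest first).
#'
#' @param x an \code{excess_summary}, or any data.frame with columns
#'   \code{stratum} and \code{mean} (and optionally \code{scenario},
#'   \code{sub_period}) such as a published projection table.
#' @param threshold_stratum first stratum counted into the numerator,
#'   e.g. \code{"50-59"}.
#' @param scenario,sub_period optional filters when \code{x} carries those
#'   columns (\code{sub_period} defaults to \code{"total"} when present).
#' @return integer percentage.
#' @examples
#' tab <- data.frame(stratum = c("0-9", "10-19", "20-29", "30-39", "40-49",
#'                               "50-59", "60-69", "70-79", "80+"),
#'                   mean = c(2, 6, 15, 30, 94, 217, 322, 409, 585))
#' age_share(tab, "50-59")   # 91
#' @export
age_share <- function(x, threshold_stratum, scenario = NULL,
                      sub_period = "total") {
  df <- if (inherits(x, "excess_summary")) x$by_age else x
  if (!is.null(scenario) && "scenario" %in% names(df))
    df <- df[df$scenario == scenario, , drop = FALSE]
  if ("sub_period" %in% names(df) && !is.null(sub_period))
    df <- df[df$sub_period == sub_period, , drop = FALSE]
  if (!nrow(df)) stop("no age rows after filtering")
  strata <- unique(df$stratum)
  i <- match(threshold_stratum, strata)
  if (is.na(i)) stop("missing stratum '", threshold_stratum, "'")
  num <- sum(df$mean[df$stratum %in% strata[i:length(strata)]])
  den <- sum(df$mean)
  as.integer(round_half_up(100 * num / den))
}

#' Project excess mortality across scenarios
#'
#' The top-level entry point: calibrates the bundle, runs paired
#' crisis/counterfactual Monte-Carlo simulations for each requested
#' scenario, and summarises excess deaths by disease, age stratum and
#' analysis sub-period with 95\% percentile intervals.
#'
#' @param bundle a \code{\link{scenario_bundle}}.
#' @param scenarios scenarios to project (default all three).
#' @param mode \code{"stochastic"} or \code{"expectation"}.
#' @param n_runs override of \code{bundle$n_runs}.
#' @return object of class \code{ncd_projection} with elements
#'   \code{summary} (an \code{excess_summary} pooled over scenarios),
#'   \code{ledgers} (per scenario), \code{bundle} (calibrated),
#'   \code{mode}.
#' @examples
#' \donttest{
#' gen <- generate_inputs(seed = 1, profile = "small")
#' proj <- project_excess(gen$bundle, n_runs = 20)
#' proj
#' }
#' @export
project_excess <- function(bundle, scenarios = projection_scenarios(),
                           mode = c("stochastic", "expectation"),
                           n_runs = NULL) {
  mode <- match.arg(mode)
  bundle <- calibrate_bundle(bundle)
  age_dists <- lapply(bundle$diseases, `[[`, "age_shares")
  ledgers <- list()
  parts <- list()
  for (sc in scenarios) {
    led <- run_projection(bundle, sc, mode = mode, n_runs = n_runs)
    ledgers[[sc]] <- led
    parts[[sc]] <- summarise_runs(led, bundle$grid, age_dists, scenario = sc)
  }
  summary <- structure(list(
    by_disease = do.call(rbind, lapply(parts, `[[`, "by_disease")),
    by_age = do.call(rbind, lapply(parts, `[[`, "by_age")),
    monthly = do.call(rbind, lapply(parts, `[[`, "monthly"))),
    class = "excess_summary")
  rownames(summary$by_disease) <- rownames(summary$by_age) <-
    rownames(summary$monthly) <- NULL
  structure(list(summary = summary, ledgers = ledgers, bundle = bundle,
                 mode = mode, scenarios = scenarios),
            class = "ncd_projection")
}

#' @export
print.ncd_projection <- function(x, ...) {
  cat("Excess NCD mortality projection (", x$mode, "mode,",
      length(x$ledgers[[1]]), "runs/scenario )\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.ncd_projection <- function(object, ...) object$summary

#' @export
coef.ncd_projection <- function(object, ...) {
  vapply(object$bundle$diseases, function(d)
    d$calibration_k %||% NA_real_, numeric(1))
}

#' @export
plot.ncd_projection <- function(x, ...) {
  m <- x$summary$monthly
  ylim <- range(0, m$crisis, m$counterfactual)
  plot(NA, xlim = range(m$month), ylim = ylim, xlab = "month index",
       ylab = "deaths/month",
       main = "Projected monthly NCD deaths by scenario", ...)
  scs <- unique(m$scenario)
  for (i in seq_along(scs)) {
    mi <- m[m$scenario == scs[i], ]
    lines(mi$month, mi$crisis, col = i + 1, lwd = 2)
  }
  mi <- m[m$scenario == scs[1], ]
  lines(mi$month, mi$counterfactual, col = "grey40", lty = 2, lwd = 2)
  legend("topleft", legend = c(scs, "counterfactual"),
         col = c(seq_along(scs) + 1, "grey40"),
         lty = c(rep(1, length(scs)), 2), lwd = 2, bty = "n")
  invisible(x)
}
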