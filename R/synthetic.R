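#' Generate a complete synthetic input bundle with known ground truth
#'
#' Emulates the statistical structure of the model's real inputs with
#' parameters known exactly, so every pipeline stage can be tested without
#' external data: log-linear annual death-count trends with Poisson noise,
#' hazard families per treatment arm in which the untreated curve dominates
#' the treated one at every time since onset, lower/upper hazard bound
#' pairs where alternative sources would disagree, uniform coverage ranges
#' nested across scenarios (ceasefire at least the status quo, status quo
#' at least escalation, pointwise), a fixed prevalent pool for the
#' insulin-dependent disease, and a nine-stratum population table. The
#' generator is structural, not empirical: it mimics scales (monthly death
#' totals of order 10 to 1000), not any real region's values.
#'
#' @param seed integer; the generator is deterministic given the seed.
#' @param profile \code{"paper_like"} — five disease groups, six baseline
#'   years, full January-2000 burn-in, 1000 runs — or \code{"small"} —
#'   three diseases (one per structural kind), a 3-year burn-in and short
#'   horizon for fast tests.
#' @param oracle compute analytic expected deaths and excess (see
#'   \code{\link{oracle_expected_deaths}}) into the ground truth; set
#'   \code{FALSE} to skip the extra work.
#' @return list with elements \code{bundle} (a
#'   \code{\link{scenario_bundle}} that passes \code{\link{validate_bundle}}
#'   with no violations) and \code{truth} (true hazard parameters, trend
#'   intercepts/slopes, coverage ranges, pool size, and — when
#'   \code{oracle} — analytic expected excess per disease, scenario and
#'   sub-period computed by a direct cohort-convolution independent of the
#'   simulation engine).
#' @export
generate_inputs <- function(seed = 1L, profile = c("paper_like", "small"),
                            oracle = TRUE) {
  profile <- match.arg(profile)
  set.seed(seed)
  grid <- if (profile == "paper_like") time_grid()
  else time_grid(war_start = 36L, n_to_date = 4L, n_proj = 3L,
                 tau_max = 36L)
  # baseline series ends in the calendar year before crisis onset
  base_years <- if (profile == "paper_like") 2017:2022 else 2000:2002

  strata <- c("0-9", "10-19", "20-29", "30-39", "40-49",
              "50-59", "60-69", "70-79", "80+")
  population <- data.frame(
    stratum = strata,
    count = c(620000, 520000, 420000, 300000, 200000,
              120000, 70000, 35000, 15000))

  old_shares <- c(0.002, 0.003, 0.01, 0.025, 0.06, 0.15, 0.25, 0.27, 0.28)
  young_shares <- c(0.10, 0.22, 0.25, 0.18, 0.11, 0.07, 0.04, 0.02, 0.01)
  mk_shares <- function(x) stats::setNames(x / sum(x), strata)

  specs <- list(
    list(id = "ihd", kind = "cvd_acute", annual0 = 1700, slope = 0.02,
         incidence = 150,
         acute = c(t = 0.05, u = 0.30),
         treated = list(fam = "exponential", p = c(rate = 0.0025)),
         untreated = list(fam = "exponential", p = c(rate = 0.010)),
         shares = mk_shares(old_shares)),
    list(id = "stroke", kind = "cvd_acute", annual0 = 600, slope = 0.015,
         incidence = 60,
         acute = c(t = 0.15, u = 0.40),
         treated = list(fam = "weibull", p = c(shape = 0.9, scale = 320)),
         untreated = list(bounds = TRUE,
                          lower = list(fam = "exponential",
                                       p = c(rate = 0.008)),
                          upper = list(fam = "exponential",
                                       p = c(rate = 0.016))),
         shares = mk_shares(old_shares)),
    list(id = "ckd_dialysis", kind = "chronic", annual0 = 360,
         slope = 0.03, incidence = 20,
         treated = list(fam = "loglogistic", p = c(alpha = 60, beta = 1.3)),
         untreated = list(fam = "exponential", p = c(rate = 0.20)),
         shares = mk_shares(c(0.01, 0.02, 0.04, 0.07, 0.12,
                              0.20, 0.24, 0.18, 0.12))),
    list(id = "cancer", kind = "chronic", annual0 = 700, slope = 0.025,
         incidence = 80,
         treated = list(fam = "loglogistic", p = c(alpha = 72, beta = 1.2)),
         untreated = list(fam = "loglogistic", p = c(alpha = 18, beta = 1.2)),
         shares = mk_shares(c(0.005, 0.01, 0.03, 0.07, 0.13,
                              0.21, 0.24, 0.19, 0.115))),
    list(id = "dm1", kind = "prevalent_pool", pool = 2000,
         treated = list(fam = "exponential", p = c(rate = 2e-4)),
         untreated = list(bounds = TRUE,
                          lower = list(fam = "exponential",
                                       p = c(rate = 0.06)),
                          upper = list(fam = "exponential",
                                       p = c(rate = 0.15))),
         shares = mk_shares(young_shares)))
  if (profile == "small") {
    ids_all <- vapply(specs, function(s) s$id, "")
    specs <- specs[ids_all %in% c("ihd", "cancer", "dm1")]
  }

  build_slot <- function(def, arm) {
    if (!is.null(def$bounds) && isTRUE(def$bounds))
      list(lower = hazard_model(def$lower$fam, def$lower$p, arm = arm,
                                bound = "lower"),
           upper = hazard_model(def$upper$fam, def$upper$p, arm = arm,
                                bound = "upper"))
    else hazard_model(def$fam, def$p, arm = arm)
  }

  diseases <- lapply(specs, function(s) {
    if (s$kind == "prevalent_pool") {
      years <- integer(); deaths <- numeric()
    } else {
      years <- base_years
      lam <- s$annual0 * exp(s$slope * (base_years - base_years[1]))
      deaths <- stats::rpois(length(base_years), lam)
    }
    disease_spec(
      id = s$id, kind = s$kind,
      hazards = list(treated = build_slot(s$treated, "treated"),
                     untreated = build_slot(s$untreated, "untreated")),
      acute = if (s$kind == "cvd_acute")
        acute_risk(s$acute[["t"]], s$acute[["u"]]),
      baseline_years = years, baseline_deaths = deaths,
      age_shares = s$shares,
      mean_incidence = s$incidence,
      prevalent_pool_size = s$pool)
  })
  names(diseases) <- vapply(diseases, `[[`, "", "id")

  # coverage: one to-date range shared across scenarios; projection ranges
  # nested pointwise ceasefire >= status_quo >= escalation
  proj_base <- list(ceasefire = c(0.50, 0.80), status_quo = c(0.30, 0.60),
                    escalation = c(0.10, 0.40))
  cov_rows <- list()
  for (id in names(diseases)) {
    shift <- stats::runif(1, -0.05, 0.05)  # per-disease access offset
    cov_rows[[length(cov_rows) + 1L]] <- data.frame(
      disease = id, period = "baseline", scenario = "baseline",
      lo = 0.90, hi = 1.00)
    td <- pmin(pmax(c(0.20, 0.50) + shift, 0), 1)
    for (sc in projection_scenarios()) {
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        disease = id, period = "to_date", scenario = sc,
        lo = td[1], hi = td[2])
      for (p in c("proj_m1_3", "proj_m4_6")) {
        r <- pmin(pmax(proj_base[[sc]] + shift, 0), 1)
        cov_rows[[length(cov_rows) + 1L]] <- data.frame(
          disease = id, period = p, scenario = sc, lo = r[1], hi = r[2])
      }
    }
  }
  coverage <- coverage_schedule(do.call(rbind, cov_rows))

  bundle <- scenario_bundle(diseases, coverage, population, grid,
                            n_runs = 1000L, seed = seed)

  truth <- list(
    profile = profile,
    hazards = lapply(specs, function(s)
      s[intersect(names(s), c("id", "treated", "untreated", "acute",
                              "pool", "incidence"))]),
    trend = do.call(rbind, lapply(specs, function(s)
      if (!is.null(s$annual0))
        data.frame(disease = s$id, intercept = log(s$annual0),
                   slope = s$slope))),
    coverage = coverage,
    pool_size = if ("dm1" %in% names(diseases)) 2000 else NULL)
  if (oracle) truth$expected_excess <- oracle_expected_excess(bundle)

  list(bundle = bundle, truth = truth)
}

#' Analytic expected monthly deaths for one disease by direct convolution
#'
#' Deterministic oracle, independent of the simulation engine: for each
#' onset cohort it propagates the closed-form survivor fraction through the
#' coverage-mixed monthly death probabilities with an explicit
#' cumulative-product convolution, and accumulates expected deaths by
#' calendar month. Used to compute ground-truth expectations for the
#' synthetic bundle and as the reference in engine tests.
#'
#' @param incidence expected incident cases per month (scalar).
#' @param q_T,q_U monthly death-probability vectors over time since onset
#'   (length at least \code{tau_max}).
#' @param coverage_path per-month coverage over the horizon.
#' @param tau_max retirement age of cohorts, months.
#' @param acute optional c(treated, untreated) acute-event death risks
#'   applied at onset before cohort entry.
#' @param pool optional prevalent-pool size; when given, a single cohort
#'   of that size enters at month \code{pool_start} (0-based) and
#'   \code{incidence} is ignored.
#' @param pool_start 0-based entry month of the pool.
#' @return numeric vector of expected deaths per month.
#' @export
oracle_expected_deaths <- function(incidence, q_T, q_U, coverage_path,
                                   tau_max, acute = NULL, pool = NULL,
                                   pool_start = 0L) {
  n <- length(coverage_path)
  deaths <- numeric(n)
  onsets <- if (is.null(pool)) 0:(n - 1L) else pool_start
  for (s in onsets) {
    entrants <- if (is.null(pool)) incidence else pool
    if (!is.null(acute)) {
      p_ac <- coverage_path[s + 1L] * acute[1] +
        (1 - coverage_path[s + 1L]) * acute[2]
      deaths[s + 1L] <- deaths[s + 1L] + entrants * p_ac
      entrants <- entrants * (1 - p_ac)
    }
    len <- min(tau_max, n - s)
    idx <- s + seq_len(len)              # calendar months, 1-based
    q <- coverage_path[idx] * q_T[seq_len(len)] +
      (1 - coverage_path[idx]) * q_U[seq_len(len)]
    alive_before <- entrants * c(1, cumprod(1 - q))[seq_len(len)]
    deaths[idx] <- deaths[idx] + alive_before * q
  }
  deaths
}

# ground-truth expected excess per disease x scenario x sub-period, built
# entirely from the oracle (trend fit, calibration and both arms), at the
# midpoint of every uniform range and the midpoint hazard-bound mixture
oracle_expected_excess <- function(bundle) {
  g <- bundle$grid
  out <- list()
  for (id in names(bundle$diseases)) {
    d <- bundle$diseases[[id]]
    q_T <- death_prob_vector(d$hazards$treated, g$tau_max, w = 0.5)
    q_U <- death_prob_vector(d$hazards$untreated, g$tau_max, w = 0.5)
    mid <- function(period, scenario)
      mean(coverage_range(bundle$coverage, id, period, scenario))
    path_for <- function(scenario) {
      path <- rep(mid("baseline", "baseline"), g$n_months)
      if (!is.null(scenario))
        for (p in analysis_periods())
          path[g$period == p] <- mid(p, scenario)
      path
    }
    sim <- function(path, incidence) {
      if (d$kind == "prevalent_pool")
        oracle_expected_deaths(0, q_T, q_U, path, g$n_months,
                               pool = d$prevalent_pool_size,
                               pool_start = g$war_start)
      else oracle_expected_deaths(
        incidence, q_T, q_U, path, g$tau_max,
        acute = if (d$kind == "cvd_acute")
          c(d$acute$treated, d$acute$untreated))
    }
    # oracle calibration to the Poisson-trend forecast
    if (d$kind == "prevalent_pool") {
      inc <- 0
    } else {
      trend <- fit_baseline_trend(d$baseline_years, d$baseline_deaths)
      target <- forecast_monthly_baseline(trend, g)
      window <- (g$war_start - 11L):g$war_start
      raw <- sim(path_for(NULL), d$mean_incidence)
      inc <- d$mean_incidence * mean(target[window]) / mean(raw[window])
    }
    base_deaths <- sim(path_for(NULL), inc)
    for (sc in projection_scenarios()) {
      crisis <- sim(path_for(sc), inc)
      for (p in c(analysis_periods(), "total")) {
        m <- if (p == "total")
          (g$war_start + 1L):g$n_months
        else period_months(g, p) + 1L
        out[[length(out) + 1L]] <- data.frame(
          disease = id, scenario = sc, sub_period = p,
          excess = sum(crisis[m] - base_deaths[m]))
      }
    }
  }
  do.call(rbind, out)
}

#' Generate noisy survival observations from a known hazard model
#'
#' Draws \eqn{x_i \sim} Binomial(\code{n_eff}, \eqn{S_{true}(\tau_i)}) at
#' each requested follow-up time and reports \eqn{x_i/n_{eff}}, matching
#' how published cohort papers report surviving proportions. Sampling can
#' make the series non-monotone; it is then clipped to non-increasing
#' (running minimum) and the clipping flagged.
#'
#' @param true_model a \code{\link{hazard_model}}.
#' @param times follow-up times, months, sorted ascending.
#' @param n_eff cohort size behind each reported proportion.
#' @param no_noise if \code{TRUE}, return the exact survival curve values
#'   (the infinite-cohort limit).
#' @return a \code{\link{survival_obs}} with attribute \code{clipped}
#'   (logical).
#' @export
generate_survival_observations <- function(true_model, times, n_eff = 1e4,
                                           no_noise = FALSE) {
  if (is.unsorted(times) || any(times <= 0))
    stop("times must be sorted ascending and positive")
  if (n_eff <= 0) stop("n_eff must be positive")
  s_true <- survival_at(true_model, times)
  s_obs <- if (no_noise) s_true
  else stats::rbinom(length(times), n_eff, s_true) / n_eff
  clipped <- any(diff(s_obs) > 0)
  s_obs <- cummin(s_obs)
  obs <- survival_obs(times, s_obs, n_eff = n_eff, arm = true_model$arm,
                      source = paste0("synthetic_", true_model$family))
  attr(obs, "clipped") <- clipped
  obs
}
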