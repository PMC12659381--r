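#' Sample a treatment-coverage value from its uniform range
#'
#' Coverage uncertainty is propagated by drawing once per run and
#' (disease, period) from Uniform(lo, hi); the draw is held constant within
#' the period for that run. Passing an explicit quantile \code{u} lets
#' paired simulation arms share the same quantile while mapping it through
#' their own ranges (common random numbers).
#'
#' @param schedule a \code{\link{coverage_schedule}}.
#' @param disease,period,scenario the range to draw from; the
#'   \code{baseline} period is scenario-free.
#' @param u uniform quantile in [0, 1]; default a fresh draw.
#' @return coverage value in [0, 1].
#' @export
sample_coverage <- function(schedule, disease, period, scenario,
                            u = stats::runif(1)) {
  r <- coverage_range(schedule, disease, period, scenario)
  unname(r["lo"] + u * (r["hi"] - r["lo"]))
}

#' Effective monthly death-probability curve from a hazard slot
#'
#' A hazard slot is either a single fitted model or a lower/upper bound
#' pair from alternative source studies. For a pair, survival uncertainty
#' is propagated by mixing the two discrete death-probability curves with a
#' weight \eqn{w \sim} Uniform(0, 1) drawn once per run:
#' \eqn{q(\tau) = w\,q_{lower}(\tau) + (1-w)\,q_{upper}(\tau)}.
#'
#' @param slot a \code{\link{hazard_model}} or \code{list(lower=, upper=)}.
#' @param w mixing weight in [0, 1] (1 = lower-bound curve); ignored for a
#'   single model. Default a fresh uniform draw.
#' @return a function of \code{tau} (months since onset, vectorised)
#'   returning monthly death probabilities.
#' @export
sample_hazard <- function(slot, w = stats::runif(1)) {
  check_hazard_slot(slot)
  if (inherits(slot, "hazard_model")) {
    force(slot)
    return(function(tau) discrete_death_prob(slot, tau))
  }
  lo <- slot$lower; hi <- slot$upper; force(w)
  function(tau) w * discrete_death_prob(lo, tau) +
    (1 - w) * discrete_death_prob(hi, tau)
}

# precomputed q(tau) vector over tau = 0 .. tau_max-1 for one arm
death_prob_vector <- function(slot, tau_max, w = 0.5, cfr_multiplier = 1) {
  q <- sample_hazard(slot, w = w)(0:(tau_max - 1))
  pmin(q * cfr_multiplier, 1)
}

## Shared monthly ledger recursion.
## `alive` holds survivors by time since onset (index i = tau i-1, months);
## each month the new cohort is prepended, the oldest retired at tau_max,
## and deaths are removed at the coverage-mixed probability
## c_t*q_T + (1-c_t)*q_U. Vectorised over tau, looped over calendar months.
ledger_recursion <- function(new_cases, q_T, q_U, coverage_path, tau_max,
                             stochastic, start_month = 0L) {
  n_months <- length(coverage_path)
  if (any(q_T < 0 | q_T > 1) || any(q_U < 0 | q_U > 1))
    stop("death probabilities must lie in [0, 1]")
  alive <- numeric(tau_max)
  deaths <- numeric(n_months)
  for (t in seq_len(n_months)) {
    if (t - 1L < start_month) next
    alive <- c(new_cases[t], alive[-tau_max])
    q <- coverage_path[t] * q_T + (1 - coverage_path[t]) * q_U
    d <- if (stochastic) stats::rbinom(tau_max, alive, q) else alive * q
    alive <- alive - d
    deaths[t] <- sum(d)
  }
  deaths
}

#' Simulate monthly deaths in a chronic-disease incident-cohort ledger
#'
#' Monthly incident cohorts enter from the start of the grid (January
#' 2000); each cohort-month, deaths occur at the coverage-mixed probability
#' \eqn{c_t q_T(\tau) + (1-c_t) q_U(\tau)} where \eqn{\tau} is the cohort's
#' time since onset, and cohorts are retired at \code{tau_max}. In
#' stochastic mode incident cases are Poisson draws around the calibrated
#' mean and deaths are binomial; expectation mode replaces every draw by
#' its mean and is the deterministic oracle the stochastic engine is tested
#' against.
#'
#' @param spec a \code{\link{disease_spec}} of kind \code{chronic} or
#'   \code{cvd_acute} (supplies the calibrated mean incidence).
#' @param coverage_path per-month coverage values over the whole grid.
#' @param q_T,q_U treated/untreated monthly death probabilities by time
#'   since onset: vectors of length \code{grid$tau_max} (or functions of
#'   tau, evaluated once).
#' @param grid a \code{\link{time_grid}}.
#' @param mode \code{"stochastic"} or \code{"expectation"}.
#' @param incident optional pre-drawn incident-case vector (one per month),
#'   used to share incidence draws between paired arms.
#' @return numeric vector of total deaths per month.
#' @export
simulate_chronic <- function(spec, coverage_path, q_T, q_U, grid,
                             mode = c("stochastic", "expectation"),
                             incident = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "time_grid"))
  if (length(coverage_path) != grid$n_months)
    stop("coverage_path must cover all ", grid$n_months, " months")
  q_T <- as_q_vector(q_T, grid$tau_max)
  q_U <- as_q_vector(q_U, grid$tau_max)
  incident <- incident %||% draw_incidence(spec, grid, mode)
  ledger_recursion(incident, q_T, q_U, coverage_path, grid$tau_max,
                   stochastic = (mode == "stochastic"))
}

as_q_vector <- function(q, tau_max) {
  if (is.function(q)) q <- q(0:(tau_max - 1))
  if (length(q) == 1L) q <- rep(q, tau_max)
  if (length(q) < tau_max)
    stop("death-probability curve must have length >= tau_max")
  q[seq_len(tau_max)]
}

# monthly incident-case draws at the calibrated mean k * I_base
draw_incidence <- function(spec, grid, mode, incidence_multiplier = 1) {
  k <- if (is.na(spec$calibration_k)) 1 else spec$calibration_k
  mu <- k * spec$mean_incidence * incidence_multiplier
  if (mode == "stochastic") stats::rpois(grid$n_months, mu)
  else rep(mu, grid$n_months)
}

#' Simulate monthly deaths for an acute-then-chronic cardiovascular disease
#'
#' The first acute presentation (heart attack, stroke) carries an immediate
#' death risk mixed by coverage,
#' \eqn{c_t \mu_{acute,T} + (1-c_t)\mu_{acute,U}}; acute survivors enter
#' the chronic ledger under the post-acute (conditioned) hazards in the
#' same onset month. With both acute risks zero this reduces exactly to
#' \code{\link{simulate_chronic}}.
#'
#' @inheritParams simulate_chronic
#' @param cfr_multiplier relative-risk multiplier applied to the acute
#'   risks (the chronic curves are scaled upstream).
#' @return numeric vector of total (acute + chronic) deaths per month.
#' @export
simulate_cvd <- function(spec, coverage_path, q_T, q_U, grid,
                         mode = c("stochastic", "expectation"),
                         incident = NULL, cfr_multiplier = 1) {
  mode <- match.arg(mode)
  if (is.null(spec$acute))
    stop_config("disease '", spec$id, "': cvd_acute simulation needs ",
                "acute risks")
  if (length(coverage_path) != grid$n_months)
    stop("coverage_path must cover all ", grid$n_months, " months")
  q_T <- as_q_vector(q_T, grid$tau_max)
  q_U <- as_q_vector(q_U, grid$tau_max)
  incident <- incident %||% draw_incidence(spec, grid, mode)

  mu_aT <- min(spec$acute$treated * cfr_multiplier, 1)
  mu_aU <- min(spec$acute$untreated * cfr_multiplier, 1)
  p_acute <- coverage_path * mu_aT + (1 - coverage_path) * mu_aU
  acute_deaths <- if (mode == "stochastic")
    stats::rbinom(grid$n_months, incident, p_acute)
  else incident * p_acute
  survivors <- incident - acute_deaths

  chronic <- ledger_recursion(survivors, q_T, q_U, coverage_path,
                              grid$tau_max,
                              stochastic = (mode == "stochastic"))
  acute_deaths + chronic
}

#' Simulate depletion of a prevalent pool from crisis onset
#'
#' For type-1 diabetes no incident cases are simulated; instead the
#' recorded prevalent pool at crisis onset depletes month by month at the
#' coverage-mixed death probability, with time since exposure counted from
#' crisis onset (individual times since diagnosis are unknown; the default
#' untreated hazard family is time-constant, so this matters little at this
#' horizon). No deaths occur before crisis onset.
#'
#' @inheritParams simulate_chronic
#' @param spec a \code{\link{disease_spec}} of kind \code{prevalent_pool}.
#' @return numeric vector of deaths per month (zero before crisis onset).
#' @export
simulate_prevalent_pool <- function(spec, coverage_path, q_T, q_U, grid,
                                    mode = c("stochastic", "expectation")) {
  mode <- match.arg(mode)
  if (is.null(spec$prevalent_pool_size) || spec$prevalent_pool_size <= 0)
    stop("prevalent pool size must be positive")
  if (length(coverage_path) != grid$n_months)
    stop("coverage_path must cover all ", grid$n_months, " months")
  n_after <- grid$n_months - grid$war_start
  q_T <- as_q_vector(q_T, n_after)
  q_U <- as_q_vector(q_U, n_after)
  new_cases <- c(spec$prevalent_pool_size, numeric(n_after - 1L))
  deaths_after <- ledger_recursion(
    new_cases, q_T, q_U,
    coverage_path[(grid$war_start + 1L):grid$n_months],
    tau_max = n_after, stochastic = (mode == "stochastic"))
  c(numeric(grid$war_start), deaths_after)
}

#' Calibrate mean incidence so counterfactual deaths match the forecast
#'
#' Simulated steady-state deaths are linear in the incident-cohort mean, so
#' the calibration multiplier \eqn{k} is the ratio of the target
#' counterfactual deaths to the deaths the raw incidence produces. The
#' engine is run in expectation mode (no Monte-Carlo noise enters \eqn{k})
#' at the midpoint of the pre-crisis coverage range over the full burn-in,
#' and means are compared over the final 12 pre-crisis months.
#'
#' @param spec a \code{\link{disease_spec}} of kind \code{chronic} or
#'   \code{cvd_acute}.
#' @param baseline_monthly forecast counterfactual deaths per month over
#'   the whole grid (from \code{\link{forecast_monthly_baseline}}).
#' @param coverage a \code{\link{coverage_schedule}} (its baseline range
#'   supplies the pre-crisis coverage midpoint).
#' @param grid a \code{\link{time_grid}}.
#' @return the multiplier \eqn{k}; also stored in the returned spec when
#'   assigned, e.g. \code{spec$calibration_k <- calibrate_incidence(...)}.
#' @export
calibrate_incidence <- function(spec, baseline_monthly, coverage, grid) {
  if (spec$kind == "prevalent_pool")
    stop("prevalent-pool diseases are not incidence-calibrated")
  window <- (grid$war_start - 11L):grid$war_start   # 1-based month indices
  target <- mean(baseline_monthly[window])
  if (target == 0) {
    warning("zero counterfactual deaths in reference window: k = 0")
    return(0)
  }
  c_mid <- mean(coverage_range(coverage, spec$id, "baseline", "baseline"))
  path <- rep(c_mid, grid$n_months)
  q_T <- death_prob_vector(spec$hazards$treated, grid$tau_max)
  q_U <- death_prob_vector(spec$hazards$untreated, grid$tau_max)
  raw_spec <- spec
  raw_spec$calibration_k <- 1
  sim <- if (spec$kind == "cvd_acute")
    simulate_cvd(raw_spec, path, q_T, q_U, grid, mode = "expectation")
  else simulate_chronic(raw_spec, path, q_T, q_U, grid,
                        mode = "expectation")
  d_prime <- mean(sim[window])
  if (d_prime <= 0)
    stop("calibration failed: simulated counterfactual deaths are zero ",
         "(are all hazards zero?)")
  target / d_prime
}
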