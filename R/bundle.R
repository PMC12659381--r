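#' Complete per-disease parameterisation
#'
#' Everything the cohort engine needs for one disease: its structural kind,
#' hazard models per treatment arm (optionally as lower/upper bound pairs
#' from alternative source studies), acute case-fatality risks for
#' cardiovascular kinds, the pre-crisis annual death series and age
#' distribution of deaths, and either a mean monthly incidence (chronic and
#' acute-CVD kinds) or a prevalent pool size (type-1 diabetes, where no
#' incident cases are simulated and baseline mortality is taken as zero).
#'
#' @param id disease identifier.
#' @param kind \code{"chronic"} (cancer, CKD), \code{"cvd_acute"}
#'   (ischaemic heart disease, stroke: an immediate acute-event death risk
#'   precedes the chronic hazard), or \code{"prevalent_pool"} (type-1
#'   diabetes: a fixed pool at crisis onset, no incidence).
#' @param hazards list with elements \code{treated} and \code{untreated};
#'   each either a single \code{\link{hazard_model}} or a
#'   \code{list(lower = , upper = )} pair of bounding models. For
#'   \code{cvd_acute} these are the post-acute (conditioned) hazards.
#' @param acute an \code{\link{acute_risk}} (cvd_acute only).
#' @param baseline_years,baseline_deaths pre-crisis annual death series
#'   (not used for \code{prevalent_pool}, whose baseline mortality is 0).
#' @param age_shares named shares of deaths by age stratum, summing to 1.
#' @param mean_incidence mean incident cases per month before calibration.
#' @param prevalent_pool_size cases alive at crisis onset
#'   (\code{prevalent_pool} only).
#' @param phi_incidence,phi_cfr relative-risk hooks multiplying incidence
#'   and both arms' death probabilities under crisis conditions; both
#'   default to 1 (treatment disruption assumed to be the only pathway).
#' @param calibration_k incidence calibration multiplier; normally left
#'   \code{NA} and filled in by \code{\link{calibrate_incidence}}.
#' @return object of class \code{disease_spec}.
#' @export
disease_spec <- function(id, kind = c("chronic", "cvd_acute",
                                      "prevalent_pool"),
                         hazards, acute = NULL,
                         baseline_years = integer(), baseline_deaths = numeric(),
                         age_shares, mean_incidence = NULL,
                         prevalent_pool_size = NULL,
                         phi_incidence = 1, phi_cfr = 1,
                         calibration_k = NA_real_) {
  kind <- match.arg(kind)
  if (!all(c("treated", "untreated") %in% names(hazards)))
    stop("hazards must have 'treated' and 'untreated' elements")
  for (arm in c("treated", "untreated")) check_hazard_slot(hazards[[arm]])
  if (kind == "cvd_acute" && !inherits(acute, "acute_risk"))
    stop_config("disease '", id, "': cvd_acute kind requires acute risks")
  if (kind == "prevalent_pool") {
    if (is.null(prevalent_pool_size) || prevalent_pool_size <= 0)
      stop("prevalent_pool kind requires a positive prevalent_pool_size")
  } else {
    if (is.null(mean_incidence) || mean_incidence <= 0)
      stop("kind '", kind, "' requires positive mean_incidence")
  }
  if (phi_incidence <= 0 || phi_cfr <= 0)
    stop("phi multipliers must be > 0")
  structure(list(
    id = id, kind = kind, hazards = hazards, acute = acute,
    baseline_years = baseline_years, baseline_deaths = baseline_deaths,
    age_shares = age_shares, mean_incidence = mean_incidence,
    prevalent_pool_size = prevalent_pool_size,
    phi_incidence = phi_incidence, phi_cfr = phi_cfr,
    calibration_k = calibration_k), class = "disease_spec")
}

check_hazard_slot <- function(h) {
  if (inherits(h, "hazard_model")) return(invisible(TRUE))
  if (is.list(h) && all(c("lower", "upper") %in% names(h)) &&
      inherits(h$lower, "hazard_model") && inherits(h$upper, "hazard_model"))
    return(invisible(TRUE))
  stop("each hazard slot must be a hazard_model or list(lower=, upper=)")
}

# all hazard_model objects held in a slot, as a flat list
hazard_slot_models <- function(h) {
  if (inherits(h, "hazard_model")) list(h) else list(h$lower, h$upper)
}

#' Treatment-coverage schedule
#'
#' Uniform coverage ranges per disease, analysis period and scenario. The
#' pre-crisis ("baseline") period default is (0.90, 1.00), reflecting
#' near-universal pre-war access to essential treatment; the counterfactual
#' arm uses the baseline range for all periods.
#'
#' @param df data.frame with columns \code{disease}, \code{period}
#'   (\code{baseline}, \code{to_date}, \code{proj_m1_3}, \code{proj_m4_6}),
#'   \code{scenario} (\code{baseline}, \code{ceasefire}, \code{status_quo},
#'   \code{escalation}), \code{lo}, \code{hi}.
#' @return the validated data.frame with class \code{coverage_schedule}.
#' @export
coverage_schedule <- function(df) {
  need <- c("disease", "period", "scenario", "lo", "hi")
  if (!all(need %in% names(df)))
    stop_config("coverage schedule needs columns: ",
                paste(need, collapse = ", "))
  bad_p <- setdiff(df$period, c("baseline", analysis_periods()))
  if (length(bad_p)) stop_config("unknown coverage period(s): ",
                                 paste(bad_p, collapse = ", "))
  bad_s <- setdiff(df$scenario, c("baseline", projection_scenarios()))
  if (length(bad_s)) stop_config("unknown scenario(s): ",
                                 paste(bad_s, collapse = ", "))
  class(df) <- c("coverage_schedule", "data.frame")
  df
}

#' Names of the three projection scenarios
#'
#' @return \code{c("ceasefire", "status_quo", "escalation")}, ordered from
#'   most to least treatment coverage.
#' @export
projection_scenarios <- function() c("ceasefire", "status_quo", "escalation")

# look up the (lo, hi) coverage range; baseline period is scenario-free
coverage_range <- function(schedule, disease, period, scenario) {
  if (period == "baseline") scenario <- "baseline"
  row <- schedule[schedule$disease == disease & schedule$period == period &
                    schedule$scenario == scenario, , drop = FALSE]
  if (nrow(row) != 1)
    stop_config("no coverage range for (", disease, ", ", period, ", ",
                scenario, ")")
  c(lo = row$lo, hi = row$hi)
}

#' Assemble a complete scenario bundle
#'
#' @param diseases list of \code{\link{disease_spec}} objects.
#' @param coverage a \code{\link{coverage_schedule}}.
#' @param population data.frame with columns \code{stratum}, \code{count}.
#' @param grid a \code{\link{time_grid}}.
#' @param n_runs Monte-Carlo runs per scenario (default 1000).
#' @param seed integer base seed for all randomness.
#' @return object of class \code{scenario_bundle}.
#' @export
scenario_bundle <- function(diseases, coverage, population,
                            grid = time_grid(), n_runs = 1000L,
                            seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  names(diseases) <- vapply(diseases, `[[`, "", "id")
  structure(list(diseases = diseases, coverage = coverage,
                 population = population, grid = grid,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("<scenario_bundle>", length(x$diseases), "diseases (",
      paste(names(x$diseases), collapse = ", "), ")\n")
  cat("  ", nrow(x$population), "age strata;", x$n_runs,
      "runs; seed", x$seed, "\n")
  print(x$grid)
  invisible(x)
}

#' Validate a scenario bundle against the model's invariants
#'
#' Pure check: returns a character vector of violation messages (empty when
#' the bundle is clean) and never throws, so callers decide severity.
#' Checks: coverage bounds ordered within [0, 1]; age distributions
#' normalised; every disease referenced by the coverage schedule exists;
#' population counts non-negative with unique strata; kind-specific fields
#' present; and — warning-level, since treatment benefit is a model
#' assumption rather than a hard constraint — untreated monthly death
#' probability at least the treated one at 1, 12, 60 and 120 months since
#' onset.
#'
#' @param bundle a \code{\link{scenario_bundle}}.
#' @return character vector of violations (empty if none).
#' @export
validate_bundle <- function(bundle) {
  v <- character()
  cov <- bundle$coverage
  for (i in seq_len(nrow(cov))) {
    if (cov$lo[i] < 0 || cov$hi[i] > 1 || cov$lo[i] > cov$hi[i])
      v <- c(v, sprintf(
        "coverage range (%.3g, %.3g) for (%s, %s, %s) violates 0 <= lo <= hi <= 1",
        cov$lo[i], cov$hi[i], cov$disease[i], cov$period[i], cov$scenario[i]))
  }
  missing_d <- setdiff(unique(cov$disease), names(bundle$diseases))
  if (length(missing_d))
    v <- c(v, paste("coverage references unknown disease(s):",
                    paste(missing_d, collapse = ", ")))
  if (any(duplicated(bundle$population$stratum)))
    v <- c(v, "population strata not unique")
  if (any(bundle$population$count < 0))
    v <- c(v, "negative population count")
  for (d in bundle$diseases) {
    if (abs(sum(d$age_shares) - 1) > 1e-9 || any(d$age_shares < 0))
      v <- c(v, paste0("disease '", d$id,
                       "': age distribution not normalised"))
    taus <- c(1, 12, 60, 120)
    qs_t <- sapply(hazard_slot_models(d$hazards$treated),
                   discrete_death_prob, tau = taus)
    qs_u <- sapply(hazard_slot_models(d$hazards$untreated),
                   discrete_death_prob, tau = taus)
    if (max(qs_t) > min(qs_u) + 1e-12 &&
        any(apply(qs_t, 1, max) > apply(qs_u, 1, min) + 1e-12))
      v <- c(v, paste0("warning: disease '", d$id, "': treated death ",
                       "probability exceeds untreated at some tau in ",
                       "{1,12,60,120} months"))
  }
  v
}
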