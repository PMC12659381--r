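#' Write a scenario bundle to a configuration directory
#'
#' Serialises a bundle as one human-readable YAML document plus delimited
#' tables, the same dialect \code{\link{load_bundle}} reads:
#' \code{config.yaml}, \code{population.csv}, \code{baseline_deaths.csv},
#' \code{age_distribution.csv}, \code{coverage.csv} and \code{hazards.csv}
#' (long format, one row per hazard parameter, with an explicit time-unit
#' column).
#'
#' @param bundle a \code{\link{scenario_bundle}}.
#' @param dir destination directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$grid
  cfg <- list(
    grid = list(war_start = g$war_start,
                n_to_date = g$to_date_end - g$war_start,
                n_proj = g$proj1_end - g$to_date_end,
                tau_max = g$tau_max),
    n_runs = bundle$n_runs,
    seed = bundle$seed,
    diseases = lapply(unname(bundle$diseases), function(d) {
      x <- list(id = d$id, kind = d$kind,
                phi_incidence = d$phi_incidence, phi_cfr = d$phi_cfr)
      if (!is.null(d$mean_incidence)) x$mean_incidence <- d$mean_incidence
      if (!is.null(d$prevalent_pool_size))
        x$prevalent_pool_size <- d$prevalent_pool_size
      if (!is.null(d$acute))
        x$acute <- list(treated = d$acute$treated,
                        untreated = d$acute$untreated)
      if (!is.na(d$calibration_k)) x$calibration_k <- d$calibration_k
      x
    }))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  utils::write.csv(bundle$population, file.path(dir, "population.csv"),
                   row.names = FALSE)

  base_rows <- do.call(rbind, lapply(bundle$diseases, function(d)
    if (length(d$baseline_years))
      data.frame(disease = d$id, year = d$baseline_years,
                 deaths = d$baseline_deaths)))
  utils::write.csv(base_rows %||% data.frame(disease = character(),
                                             year = integer(),
                                             deaths = numeric()),
                   file.path(dir, "baseline_deaths.csv"), row.names = FALSE)

  age_rows <- do.call(rbind, lapply(bundle$diseases, function(d)
    data.frame(disease = d$id, stratum = names(d$age_shares),
               share = unname(d$age_shares))))
  utils::write.csv(age_rows, file.path(dir, "age_distribution.csv"),
                   row.names = FALSE)

  utils::write.csv(as.data.frame(bundle$coverage),
                   file.path(dir, "coverage.csv"), row.names = FALSE)

  haz_rows <- do.call(rbind, lapply(bundle$diseases, function(d) {
    do.call(rbind, lapply(c("treated", "untreated"), function(arm) {
      do.call(rbind, lapply(hazard_slot_models(d$hazards[[arm]]),
                            function(m)
        data.frame(disease = d$id, arm = arm, bound = m$bound,
                   family = m$family, unit = m$unit,
                   param = names(m$params), value = unname(m$params))))
    }))
  }))
  utils::write.csv(haz_rows, file.path(dir, "hazards.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a scenario bundle from a configuration directory
#'
#' Reads the YAML document and tables written by \code{\link{write_bundle}}
#' (or assembled by hand to the same schema), converts every hazard
#' parameter to per-month units — a missing time-unit label is an error,
#' never silently defaulted — and applies defaults (\code{n_runs} 1000,
#' relative-risk multipliers 1). Optional per-disease config fields:
#' \code{baseline_scale} (a plain ratio multiplying the annual death series,
#' e.g. a population scaling between regions) and, at top level,
#' \code{stroke_split} (\code{combined}, \code{into}): a combined stroke
#' death series is split 50/50 into ischaemic and haemorrhagic series at
#' load.
#'
#' @param dir directory containing \code{config.yaml} and its tables.
#' @return a \code{\link{scenario_bundle}}.
#' @export
load_bundle <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) stop_config("missing config.yaml in ", dir)
  cfg <- yaml::read_yaml(cfg_path)
  for (key in c("grid", "diseases"))
    if (is.null(cfg[[key]]))
      stop_config("configuration missing required key '", key, "'")

  read_tab <- function(name, required = TRUE) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      if (required) stop_config("missing required table ", name)
      return(NULL)
    }
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  population <- read_tab("population.csv")
  baseline <- read_tab("baseline_deaths.csv")
  ages <- read_tab("age_distribution.csv")
  cov <- coverage_schedule(read_tab("coverage.csv"))
  haz <- read_tab("hazards.csv")
  if (is.null(haz$unit) || any(is.na(haz$unit) | haz$unit == ""))
    stop_config("hazards.csv must carry a time unit ('month' or 'year') ",
                "on every survival parameter")

  if (!is.null(cfg$stroke_split))
    baseline <- split_combined_stroke(baseline,
                                      combined = cfg$stroke_split$combined,
                                      into = cfg$stroke_split$into)

  grid <- time_grid(war_start = cfg$grid$war_start,
                    n_to_date = cfg$grid$n_to_date %||% 4L,
                    n_proj = cfg$grid$n_proj %||% 3L,
                    tau_max = cfg$grid$tau_max)

  build_slot <- function(rows) {
    one <- function(r) {
      p <- stats::setNames(r$value, r$param)
      convert_hazard_units(hazard_model(r$family[1], p, arm = r$arm[1],
                                        bound = r$bound[1],
                                        unit = r$unit[1]))
    }
    if (all(rows$bound == "point")) return(one(rows))
    list(lower = one(rows[rows$bound == "lower", , drop = FALSE]),
         upper = one(rows[rows$bound == "upper", , drop = FALSE]))
  }

  diseases <- lapply(cfg$diseases, function(dc) {
    id <- dc$id %||% stop_config("disease entry missing required key 'id'")
    hz <- haz[haz$disease == id, , drop = FALSE]
    if (!nrow(hz)) stop_config("no hazard parameters for disease '", id, "'")
    hazards <- lapply(c(treated = "treated", untreated = "untreated"),
                      function(arm) {
      rows <- hz[hz$arm == arm, , drop = FALSE]
      if (!nrow(rows))
        stop_config("disease '", id, "': no ", arm, " hazard parameters")
      build_slot(rows)
    })
    bs <- baseline[baseline$disease == id, , drop = FALSE]
    ag <- ages[ages$disease == id, , drop = FALSE]
    if (!nrow(ag)) stop_config("disease '", id, "': no age distribution")
    scale <- dc$baseline_scale %||% 1
    disease_spec(
      id = id, kind = dc$kind %||% "chronic", hazards = hazards,
      acute = if (!is.null(dc$acute))
        acute_risk(dc$acute$treated, dc$acute$untreated),
      baseline_years = bs$year, baseline_deaths = bs$deaths * scale,
      age_shares = stats::setNames(ag$share, ag$stratum),
      mean_incidence = dc$mean_incidence,
      prevalent_pool_size = dc$prevalent_pool_size,
      phi_incidence = dc$phi_incidence %||% 1,
      phi_cfr = dc$phi_cfr %||% 1,
      calibration_k = dc$calibration_k %||% NA_real_)
  })

  scenario_bundle(diseases, cov, population, grid,
                  n_runs = cfg$n_runs %||% 1000L,
                  seed = cfg$seed %||% 1L)
}

#' Split a combined stroke death series into ischaemic and haemorrhagic
#'
#' Registries often report stroke as a single cause, but ischaemic and
#' haemorrhagic stroke have very different survival. The split assumes 50%
#' of combined stroke deaths are of each type.
#'
#' @param baseline data.frame with columns \code{disease}, \code{year},
#'   \code{deaths}.
#' @param combined name of the combined series to split.
#' @param into the two replacement disease ids.
#' @return the baseline data.frame with the combined rows replaced.
#' @export
split_combined_stroke <- function(baseline, combined = "stroke",
                                  into = c("stroke_ischaemic",
                                           "stroke_haemorrhagic")) {
  sel <- baseline$disease == combined
  if (!any(sel)) return(baseline)
  half <- baseline[sel, , drop = FALSE]
  half$deaths <- half$deaths / 2
  rbind(baseline[!sel, , drop = FALSE],
        transform(half, disease = into[1]),
        transform(half, disease = into[2]))
}

#' Write the three report tables of an excess-mortality summary
#'
#' Writes delimited tables mirroring the published layout: excess deaths by
#' disease, scenario and sub-period; by age stratum, scenario and
#' sub-period; and the monthly death trajectories (crisis, counterfactual
#' and excess means). Means and percentile bounds are rounded half-up to
#' integers and printed with thousands separators at write time only — all
#' upstream arithmetic is on reals.
#'
#' @param summary an \code{excess_summary} (see
#'   \code{\link{summarise_runs}}).
#' @param dir destination directory.
#' @return character vector of the files written, invisibly.
#' @export
write_tables <- function(summary, dir) {
  stopifnot(inherits(summary, "excess_summary"))
  if (!nrow(summary$by_disease)) stop("nothing to write: empty summary")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  fmt <- function(df) {
    for (col in intersect(c("mean", "pi_lo", "pi_hi", "mean_crisis",
                            "mean_counterfactual"), names(df)))
      df[[col]] <- format_count(df[[col]])
    df
  }
  paths <- file.path(dir, c("excess_by_disease.csv", "excess_by_age.csv",
                            "monthly_deaths.csv"))
  utils::write.csv(fmt(summary$by_disease), paths[1], row.names = FALSE)
  utils::write.csv(fmt(summary$by_age), paths[2], row.names = FALSE)
  utils::write.csv(summary$monthly, paths[3], row.names = FALSE)
  invisible(paths)
}
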