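#' Monthly simulation time grid
#'
#' The engine works on a discrete monthly grid whose origin is January 2000
#' (month index 0). Month boundaries follow the 7th-to-6th convention of the
#' analysis periods: month \eqn{m} runs from the 7th of calendar month
#' \code{origin + m} to the 6th of the following calendar month, so that the
#' "to date" window (7 Oct 2023 to 6 Feb 2024) and the two three-month
#' projection windows align exactly with month indices.
#'
#' @param war_start month index of crisis onset; the default 285 is
#'   October 2023 on a January-2000 origin.
#' @param n_to_date length of the "to date" window, months.
#' @param n_proj length of each projection sub-period, months.
#' @param tau_max maximum tracked time since disease onset, months; cohorts
#'   are retired beyond this age. Defaults to the burn-in length so that the
#'   oldest cohort alive at crisis onset dates from the simulation origin.
#'
#' @return An object of class \code{time_grid}: a list with the month index
#'   of each period boundary, the total horizon \code{n_months}, and a
#'   \code{period} factor of length \code{n_months} labelling every month as
#'   \code{burn_in}, \code{to_date}, \code{proj_m1_3} or \code{proj_m4_6}.
#' @examples
#' g <- time_grid()
#' table(g$period)
#' @export
time_grid <- function(war_start = 285L, n_to_date = 4L, n_proj = 3L,
                      tau_max = NULL) {
  war_start <- as.integer(war_start)
  if (war_start <= 0L) stop("war_start must be after the grid origin")
  if (n_to_date < 1L || n_proj < 1L) stop("period lengths must be >= 1 month")
  if (is.null(tau_max)) tau_max <- war_start
  tau_max <- as.integer(tau_max)
  if (tau_max < 1L) stop("tau_max must be >= 1 month")

  to_date_end <- war_start + n_to_date          # exclusive
  proj1_end   <- to_date_end + n_proj
  proj2_end   <- proj1_end + n_proj
  n_months    <- proj2_end
  period <- rep(c("burn_in", "to_date", "proj_m1_3", "proj_m4_6"),
                times = c(war_start, n_to_date, n_proj, n_proj))
  structure(list(
    origin_year = 2000L,
    dt          = 1L,
    war_start   = war_start,
    to_date_end = to_date_end,
    proj1_end   = proj1_end,
    proj2_end   = proj2_end,
    n_months    = n_months,
    tau_max     = tau_max,
    period      = period
  ), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Monthly time grid (origin Jan", x$origin_year,
      "= month 0, 7th-to-6th months)\n")
  cat("  crisis onset: month", x$war_start, "\n")
  cat("  horizon:", x$n_months, "months; tau_max:", x$tau_max, "months\n")
  cat("  periods:", paste(sprintf("%s=%d", names(table(x$period)),
                                  table(x$period)), collapse = ", "), "\n")
  invisible(x)
}

#' Calendar year containing the start day of a grid month
#'
#' Month \code{m} starts on the 7th of calendar month \code{origin + m}; the
#' year of that start day is what baseline forecasting uses when a monthly
#' slice straddles a calendar year boundary.
#'
#' @param grid a \code{time_grid}.
#' @param month month index (0-based) or vector of indices.
#' @return integer calendar years.
#' @export
grid_month_year <- function(grid, month) {
  grid$origin_year + as.integer(month) %/% 12L
}

## sub-period labels used throughout reporting
analysis_periods <- function() c("to_date", "proj_m1_3", "proj_m4_6")

period_months <- function(grid, period) {
  which(grid$period == period) - 1L   # 0-based month indices
}
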