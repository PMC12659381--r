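#' Fit a log-linear Poisson trend to pre-crisis annual death counts
#'
#' Fits \code{deaths ~ year} with a Poisson GLM (log link), the standard
#' short-series trend model for registry counts. Years are centred at the
#' first data year for numerical stability. With a single year of data the
#' trend is flat (slope 0, with a warning); with exactly two years the fit
#' interpolates both counts exactly.
#'
#' @param years calendar years, consecutive.
#' @param deaths non-negative annual death counts, same length.
#' @return object of class \code{baseline_trend} with elements
#'   \code{intercept} (log annual rate at \code{ref_year}), \code{slope}
#'   (log-rate change per year), \code{ref_year}, and the input series.
#' @examples
#' tr <- fit_baseline_trend(2021:2022, c(100, 110))
#' predict(tr, 2023)   # 121: the 1.1x annual ratio carried forward
#' @export
fit_baseline_trend <- function(years, deaths) {
  if (length(years) != length(deaths) || !length(years))
    stop("years and deaths must be equal-length, non-empty")
  if (any(deaths < 0)) stop("death counts must be non-negative")
  if (length(years) > 1 && any(diff(sort(years)) != 1))
    stop("years must be consecutive")
  ref <- min(years)
  if (length(years) == 1) {
    warning("single year of baseline data: flat (zero-slope) forecast")
    intercept <- if (deaths > 0) log(deaths) else -Inf
    slope <- 0
  } else if (all(deaths == 0)) {
    intercept <- -Inf
    slope <- 0
  } else {
    fit <- stats::glm(deaths ~ I(years - ref), family = stats::poisson())
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  structure(list(intercept = intercept, slope = slope, ref_year = ref,
                 years = years, deaths = deaths),
            class = "baseline_trend")
}

#' @export
coef.baseline_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Forecast annual death counts from a fitted trend
#'
#' @param object a \code{baseline_trend}.
#' @param years calendar years to forecast (default: two years past the
#'   data).
#' @param ... unused.
#' @return named numeric vector of expected annual deaths.
#' @export
predict.baseline_trend <- function(object, years = NULL, ...) {
  if (is.null(years))
    years <- (max(object$years) + 1):(max(object$years) + 2)
  if (is.infinite(object$intercept))
    return(stats::setNames(rep(0, length(years)), years))
  stats::setNames(
    exp(object$intercept + object$slope * (years - object$ref_year)), years)
}

#' @export
print.baseline_trend <- function(x, ...) {
  cat(sprintf(
    "<baseline_trend> %d year(s) %d-%d; annual rate %.1f at %d, x%.4f/year\n",
    length(x$years), min(x$years), max(x$years),
    if (is.infinite(x$intercept)) 0 else exp(x$intercept),
    x$ref_year, exp(x$slope)))
  invisible(x)
}

#' Discretise a fitted annual trend to monthly expected deaths
#'
#' Each grid month takes one twelfth of the fitted annual rate of the
#' calendar year containing the month's start day (months straddle calendar
#' years under the 7th-to-6th convention). The twelve months starting within
#' a year therefore sum exactly to that year's annual forecast.
#'
#' @param trend a \code{baseline_trend}.
#' @param grid a \code{\link{time_grid}}.
#' @param months month indices to forecast; default the whole grid horizon.
#' @return numeric vector of expected deaths per month, one per entry of
#'   \code{months}.
#' @export
forecast_monthly_baseline <- function(trend, grid, months = NULL) {
  stopifnot(inherits(trend, "baseline_trend"), inherits(grid, "time_grid"))
  months <- months %||% (seq_len(grid$n_months) - 1L)
  if (!length(months)) stop("forecast horizon must be positive")
  yrs <- grid_month_year(grid, months)
  annual <- predict(trend, years = sort(unique(yrs)))
  unname(annual[as.character(yrs)]) / 12
}

#' Allocate deaths across age strata by a fixed age distribution
#'
#' The age distribution of deaths is assumed unchanged by the crisis, so any
#' death total (baseline, crisis or excess) is spread across the nine age
#' strata proportionally. Values stay real; rounding happens only when
#' tables are written.
#'
#' @param deaths a death count (or vector over e.g. runs or months).
#' @param shares named numeric vector of age-stratum shares summing to 1.
#' @return matrix with one row per element of \code{deaths} and one column
#'   per stratum (a named vector when \code{deaths} is scalar).
#' @export
allocate_by_age <- function(deaths, shares) {
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9)
    stop("age distribution not normalised (shares must be >= 0, sum to 1)")
  out <- outer(deaths, shares)
  if (length(deaths) == 1L) out[1, ] else out
}
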