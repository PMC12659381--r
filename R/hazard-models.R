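#' Parametric hazard model for one disease and treatment arm
#'
#' Represents one of four candidate survival families on the monthly time
#' scale. All parameters are in per-month units: the engine never sees
#' per-year quantities (see \code{\link{convert_hazard_units}}).
#'
#' Families and their hazards \eqn{\mu(\tau)} for time since onset
#' \eqn{\tau > 0} (months):
#' \itemize{
#'   \item exponential: \eqn{\mu(\tau) = \lambda} (constant);
#'   \item Weibull: \eqn{\mu(\tau) = (k/s)(\tau/s)^{k-1}} with shape
#'     \eqn{k} and scale \eqn{s};
#'   \item log-normal: \eqn{\mu(\tau) = \phi(z) / (\sigma \tau (1-\Phi(z)))}
#'     with \eqn{z = (\ln\tau - \mu)/\sigma};
#'   \item log-logistic: \eqn{\mu(\tau) = (\beta/\alpha)(\tau/\alpha)^{\beta-1}
#'     / (1 + (\tau/\alpha)^\beta)}.
#' }
#'
#' @param family one of \code{"exponential"}, \code{"weibull"},
#'   \code{"lognormal"}, \code{"loglogistic"}.
#' @param params named numeric vector of family parameters
#'   (\code{rate}; \code{shape}, \code{scale}; \code{meanlog}, \code{sdlog};
#'   \code{alpha}, \code{beta}).
#' @param arm \code{"treated"} or \code{"untreated"}.
#' @param bound \code{"point"}, \code{"lower"} or \code{"upper"} — whether
#'   this curve is a single estimate or one of a pair of bounding fits from
#'   alternative source studies.
#' @param unit time unit of the parameters; anything other than
#'   \code{"month"} must go through \code{\link{convert_hazard_units}}
#'   before use.
#' @return object of class \code{hazard_model}.
#' @examples
#' m <- hazard_model("exponential", c(rate = 0.02))
#' hazard_at(m, 7)         # 0.02, constant hazard
#' survival_at(m, 12)      # exp(-0.24)
#' @export
hazard_model <- function(family = c("exponential", "weibull", "lognormal",
                                    "loglogistic"),
                         params, arm = "untreated", bound = "point",
                         unit = "month") {
  family <- match.arg(family)
  params <- unlist(params)
  needed <- hazard_param_names(family)
  if (!all(needed %in% names(params)))
    stop("family '", family, "' needs parameters: ",
         paste(needed, collapse = ", "))
  params <- params[needed]
  check_hazard_params(family, params)
  if (!arm %in% c("treated", "untreated"))
    stop("arm must be 'treated' or 'untreated'")
  if (!bound %in% c("point", "lower", "upper"))
    stop("bound must be 'point', 'lower' or 'upper'")
  structure(list(family = family, params = params, arm = arm,
                 bound = bound, unit = unit),
            class = "hazard_model")
}

hazard_param_names <- function(family) {
  switch(family,
         exponential = "rate",
         weibull     = c("shape", "scale"),
         lognormal   = c("meanlog", "sdlog"),
         loglogistic = c("alpha", "beta"))
}

check_hazard_params <- function(family, params) {
  bad <- switch(family,
    exponential = params[["rate"]] < 0,
    weibull     = params[["shape"]] <= 0 || params[["scale"]] <= 0,
    lognormal   = params[["sdlog"]] <= 0,
    loglogistic = params[["alpha"]] <= 0 || params[["beta"]] <= 0)
  if (is.na(bad) || bad)
    stop("invalid parameters for family '", family, "': ",
         paste(sprintf("%s=%g", names(params), params), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf("<hazard_model> %s (%s arm, %s), per-%s\n  %s\n",
              x$family, x$arm, x$bound, x$unit,
              paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' Convert hazard-model parameters between yearly and monthly time units
#'
#' Survival parameters extracted from the clinical literature are usually on
#' a yearly scale; the engine is monthly. A change of time unit by factor 12
#' rescales: exponential rate divided by 12; Weibull and log-logistic scale
#' parameters multiplied by 12 (shapes unchanged); log-normal location
#' shifted by \eqn{+\ln 12} (spread unchanged). The conversion is a no-op on
#' a model already in months, so it is idempotent.
#'
#' @param model a \code{hazard_model}.
#' @return the model with parameters in per-month units and
#'   \code{unit = "month"}.
#' @export
convert_hazard_units <- function(model) {
  stopifnot(inherits(model, "hazard_model"))
  if (model$unit %in% c("month", "months")) {
    model$unit <- "month"
    return(model)
  }
  if (!model$unit %in% c("year", "years"))
    stop("unknown time unit '", model$unit,
         "' on hazard parameters (use 'month' or 'year')")
  p <- model$params
  model$params <- switch(model$family,
    exponential = c(rate = unname(p[["rate"]]) / 12),
    weibull     = c(shape = unname(p[["shape"]]),
                    scale = unname(p[["scale"]]) * 12),
    lognormal   = c(meanlog = unname(p[["meanlog"]]) + log(12),
                    sdlog   = unname(p[["sdlog"]])),
    loglogistic = c(alpha = unname(p[["alpha"]]) * 12,
                    beta  = unname(p[["beta"]])))
  model$unit <- "month"
  model
}

#' Instantaneous hazard at a time since onset
#'
#' @param model a \code{hazard_model} (per-month units).
#' @param tau time since disease onset, months; strictly positive. Vectorised.
#' @return non-negative hazard per month.
#' @export
hazard_at <- function(model, tau) {
  stopifnot(inherits(model, "hazard_model"))
  if (any(tau <= 0)) stop("tau must be > 0")
  p <- model$params
  switch(model$family,
    exponential = rep_len(p[["rate"]], length(tau)),
    weibull = {
      k <- p[["shape"]]; s <- p[["scale"]]
      (k / s) * (tau / s)^(k - 1)
    },
    lognormal = {
      z <- (log(tau) - p[["meanlog"]]) / p[["sdlog"]]
      stats::dnorm(z) / (p[["sdlog"]] * tau *
                           stats::pnorm(z, lower.tail = FALSE))
    },
    loglogistic = {
      a <- p[["alpha"]]; b <- p[["beta"]]
      r <- (tau / a)^b
      (b / tau) * r / (1 + r)
    })
}

#' Proportion surviving to a time since onset
#'
#' Closed-form survival paired with each hazard so that
#' \eqn{\mu(\tau) = -d \ln S / d\tau} exactly.
#'
#' @param model a \code{hazard_model} (per-month units).
#' @param tau time since onset, months; non-negative. Vectorised.
#' @return survival proportion in (0, 1]; 1 at \code{tau = 0}.
#' @export
survival_at <- function(model, tau) {
  stopifnot(inherits(model, "hazard_model"))
  if (any(tau < 0)) stop("tau must be >= 0")
  p <- model$params
  switch(model$family,
    exponential = exp(-p[["rate"]] * tau),
    weibull     = exp(-(tau / p[["scale"]])^p[["shape"]]),
    lognormal   = ifelse(tau == 0, 1,
                         stats::pnorm((log(pmax(tau, .Machine$double.xmin)) -
                                         p[["meanlog"]]) / p[["sdlog"]],
                                      lower.tail = FALSE)),
    loglogistic = 1 / (1 + (tau / p[["alpha"]])^p[["beta"]]))
}

#' Monthly discrete death probability
#'
#' Probability of dying during the month \eqn{[\tau, \tau+1)} conditional on
#' being alive at \eqn{\tau}: \eqn{q(\tau) = 1 - S(\tau+1)/S(\tau)}. This is
#' the per-step case fatality the cohort engine applies.
#'
#' @inheritParams survival_at
#' @return probability in [0, 1). Vectorised over \code{tau}.
#' @export
discrete_death_prob <- function(model, tau) {
  s0 <- survival_at(model, tau)
  s1 <- survival_at(model, tau + 1)
  q <- 1 - s1 / s0
  pmin(pmax(q, 0), 1)   # guard tiny negative from floating point
}

#' Survival observation series extracted from a cohort study
#'
#' A set of (time, proportion surviving) points for one disease and
#' treatment arm, as read off published follow-up studies, with an effective
#' cohort size driving the binomial fitting weight.
#'
#' @param tau follow-up times, months, strictly positive.
#' @param surviving proportions surviving at \code{tau}, in [0, 1].
#' @param n_eff effective cohort size(s); recycled. When the source reports
#'   none, 100 is used, a deliberately weak weight.
#' @param arm \code{"treated"} or \code{"untreated"}.
#' @param source free-text citation tag.
#' @return data.frame of class \code{survival_obs} with columns
#'   \code{tau}, \code{surviving}, \code{n_eff}, \code{arm}, \code{source}.
#' @export
survival_obs <- function(tau, surviving, n_eff = 100L,
                         arm = "untreated", source = "unspecified") {
  if (any(tau <= 0)) stop("follow-up times must be > 0")
  if (any(surviving < 0 | surviving > 1))
    stop("surviving must be within [0, 1]")
  if (any(n_eff <= 0)) stop("n_eff must be positive")
  d <- data.frame(tau = as.numeric(tau), surviving = as.numeric(surviving),
                  n_eff = as.integer(rep_len(n_eff, length(tau))),
                  arm = arm, source = source, stringsAsFactors = FALSE)
  d <- d[order(d$tau), , drop = FALSE]
  for (src in unique(d$source)) {
    sel <- d$source == src
    if (is.unsorted(rev(d$surviving[sel]), strictly = FALSE) &&
        any(diff(d$surviving[sel]) > 1e-12))
      warning("surviving is not non-increasing in tau for source '",
              src, "'")
  }
  class(d) <- c("survival_obs", class(d))
  d
}

#' Condition observed survival on having survived the acute event
#'
#' For cardiovascular disease the first acute presentation (heart attack,
#' stroke) carries an immediate death risk \eqn{\mu_{acute}}; long-term
#' cohort survival from the literature includes those acute deaths. Dividing
#' each observed proportion by \eqn{1 - \mu_{acute}} gives survival
#' conditional on surviving the acute event, which is what the post-acute
#' hazard should be fitted to.
#'
#' @param obs a \code{survival_obs} data frame.
#' @param mu_acute acute case-fatality risk in [0, 1) for the same arm as
#'   \code{obs}.
#' @return \code{obs} with \code{surviving} replaced by the conditional
#'   proportions.
#' @export
condition_on_acute_survival <- function(obs, mu_acute) {
  stopifnot(inherits(obs, "survival_obs"))
  if (mu_acute < 0 || mu_acute >= 1)
    stop("mu_acute must be in [0, 1); 1 would leave no acute survivors")
  if (any(obs$surviving > 1 - mu_acute + 1e-12))
    stop("observed survival exceeds 1 - mu_acute: overall survival must ",
         "include acute deaths")
  obs$surviving <- pmin(obs$surviving / (1 - mu_acute), 1)
  obs
}

#' Acute case-fatality risks for cardiovascular events
#'
#' @param treated,untreated probability of death at the first acute event,
#'   in [0, 1), for treated and untreated cases.
#' @return list of class \code{acute_risk}.
#' @export
acute_risk <- function(treated, untreated) {
  if (any(c(treated, untreated) < 0) || any(c(treated, untreated) >= 1))
    stop("acute risks must be in [0, 1)")
  if (untreated < treated)
    warning("untreated acute risk below treated acute risk")
  structure(list(treated = treated, untreated = untreated),
            class = "acute_risk")
}
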