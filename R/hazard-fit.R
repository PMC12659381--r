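#' Fit parametric survival families to literature survival points
#'
#' Fits each candidate family to a series of (follow-up time, proportion
#' surviving) observations by maximum likelihood and ranks the families.
#' Because only aggregate proportions are available (no individual-level
#' follow-up), the likelihood treats each reported time point as an
#' independent binomial draw: with \eqn{x_i = \mathrm{round}(n_i s_i)}
#' survivors out of \eqn{n_i} at time \eqn{\tau_i},
#' \deqn{\ell = \sum_i x_i \ln S(\tau_i) + (n_i - x_i) \ln(1 - S(\tau_i)).}
#' This ignores the nesting of survivors across time points within one
#' cohort and is an acknowledged approximation.
#'
#' Optimisation is over log-transformed parameters with a deterministic
#' multi-start grid anchored at the empirical median survival time, so fits
#' are reproducible and robust to local optima. Families needing two
#' parameters are skipped (with a warning) when fewer than two distinct
#' follow-up times are available.
#'
#' @param obs a \code{\link{survival_obs}} data frame.
#' @param families candidate families to fit; any subset of
#'   \code{c("exponential", "weibull", "lognormal", "loglogistic")}.
#' @param criterion \code{"loglik"} ranks by raw maximised log-likelihood
#'   (the default); \code{"aic"} penalises parameter count.
#' @param arm,bound metadata stamped onto the fitted \code{hazard_model}s.
#' @return object of class \code{hazard_fit_list}: a list of
#'   \code{hazard_fit} objects sorted best-first, each with elements
#'   \code{model}, \code{logLik}, \code{aic}, \code{npar}, \code{converged}.
#'   The selected model is \code{fits[[1]]$model}.
#' @examples
#' obs <- survival_obs(tau = 12, surviving = 0.5, n_eff = 1000)
#' f <- fit_survival_model(obs, families = "exponential")
#' coef(f[[1]])               # rate = log(2)/12
#' @export
fit_survival_model <- function(obs,
                               families = c("exponential", "weibull",
                                            "lognormal", "loglogistic"),
                               criterion = c("loglik", "aic"),
                               arm = NULL, bound = "point") {
  stopifnot(inherits(obs, "survival_obs"))
  if (nrow(obs) < 1) stop("need at least one survival observation")
  families <- match.arg(families, several.ok = TRUE)
  criterion <- match.arg(criterion)
  arm <- arm %||% obs$arm[1]

  n_distinct <- length(unique(obs$tau))
  fits <- list()
  for (fam in families) {
    npar <- length(hazard_param_names(fam))
    if (npar > 1 && n_distinct < 2) {
      warning("family '", fam, "' needs >= 2 distinct follow-up times; ",
              "skipped")
      next
    }
    fit <- fit_one_family(obs, fam, arm, bound)
    if (is.null(fit)) {
      warning("family '", fam, "' failed to converge; skipped")
      next
    }
    fits[[fam]] <- fit
  }
  if (!length(fits)) stop("no family could be fitted to the observations")
  score <- vapply(fits, function(f)
    if (criterion == "aic") -f$aic else f$logLik, numeric(1))
  fits <- fits[order(score, decreasing = TRUE)]
  structure(fits, class = "hazard_fit_list", criterion = criterion)
}

# binomial log-likelihood of a survival curve against the observations
binom_loglik <- function(model, obs) {
  s <- survival_at(model, obs$tau)
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  x <- round(obs$n_eff * obs$surviving)
  sum(x * log(s) + (obs$n_eff - x) * log(1 - s))
}

# rough empirical median survival time used to anchor start values
empirical_median_tau <- function(obs) {
  if (all(obs$surviving > 0.5)) return(max(obs$tau) * 2)
  if (all(obs$surviving < 0.5)) return(min(obs$tau) / 2)
  if (length(unique(obs$surviving)) < 2) {
    s <- obs$surviving[1]
    if (s > 0 && s < 1) return(obs$tau[1] * log(0.5) / log(s))
    return(obs$tau[1])
  }
  stats::approx(obs$surviving, obs$tau, xout = 0.5, ties = mean)$y
}

fit_one_family <- function(obs, family, arm, bound) {
  m50 <- max(empirical_median_tau(obs), 1e-3)
  make <- function(p) hazard_model(family, p, arm = arm, bound = bound)
  negll <- function(logp, names) {
    p <- stats::setNames(exp(logp), names)
    if (family == "lognormal") p[["meanlog"]] <- logp[1]  # location: real line
    -binom_loglik(make(p), obs)
  }

  if (family == "exponential") {
    opt <- stats::optimize(function(lr) negll(lr, "rate"),
                           interval = log(c(1e-8, 10)), tol = 1e-12)
    par <- c(rate = exp(opt$minimum))
    ll <- -opt$objective
    return(new_hazard_fit(make(par), ll, 1L, TRUE))
  }

  nm <- hazard_param_names(family)
  starts <- switch(family,
    weibull = lapply(c(0.5, 1, 1.5, 3), function(k)
      c(log(k), log(m50 / log(2)^(1 / k)))),       # shape, scale
    lognormal = lapply(c(0.25, 0.5, 1, 2), function(s)
      c(log(m50), log(s))),                        # meanlog (real), sdlog
    loglogistic = lapply(c(0.5, 1, 1.5, 3), function(b)
      c(log(m50), log(b))))                        # alpha, beta
  # parameter order must match hazard_param_names
  if (family == "weibull") nm_ord <- c("shape", "scale") else nm_ord <- nm

  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, negll, names = nm_ord, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o)) next
    o <- tryCatch(    # polish
      stats::optim(o$par, negll, names = nm_ord, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) o)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) return(NULL)
  p <- stats::setNames(exp(best$par), nm_ord)
  if (family == "lognormal") p[["meanlog"]] <- best$par[1]
  new_hazard_fit(make(p[hazard_param_names(family)]), -best$value,
                 2L, best$convergence == 0)
}

new_hazard_fit <- function(model, logLik, npar, converged) {
  structure(list(model = model, logLik = logLik, npar = npar,
                 aic = 2 * npar - 2 * logLik, converged = converged),
            class = "hazard_fit")
}

#' @export
coef.hazard_fit <- function(object, ...) object$model$params

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> %s  logLik %.3f  AIC %.3f%s\n  %s\n",
              x$model$family, x$logLik, x$aic,
              if (x$converged) "" else "  (not converged)",
              paste(sprintf("%s = %.6g", names(x$model$params),
                            x$model$params), collapse = ", ")))
  invisible(x)
}

#' @export
print.hazard_fit_list <- function(x, ...) {
  cat("Fitted survival families (best first, by",
      attr(x, "criterion"), "):\n")
  for (f in x) print(f)
  invisible(x)
}
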