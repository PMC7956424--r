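#' Parametric survival laws
#'
#' A `parametric_survival` object represents one of four survival families
#' with time measured in months. The Weibull uses the rate-shape convention
#' \eqn{S(t) = \exp(-\lambda t^\gamma)}, the parameterization under which the
#' IMbrave 150 sorafenib curves are commonly reported (overall survival
#' \eqn{\lambda = 0.027, \gamma = 1.286}; progression-free survival
#' \eqn{\lambda = 0.093, \gamma = 1.312}); other conventions are converted at
#' this boundary.
#'
#' Families and parameters:
#' * `weibull`: `rate` (\eqn{\lambda}), `shape` (\eqn{\gamma});
#'   \eqn{S(t)=\exp(-\lambda t^\gamma)}.
#' * `exponential`: `rate`; \eqn{S(t)=\exp(-\lambda t)}.
#' * `log_logistic`: `scale` (\eqn{\alpha}), `shape` (\eqn{\beta});
#'   \eqn{S(t)=1/(1+(t/\alpha)^\beta)}.
#' * `log_normal`: `meanlog`, `sdlog`; \eqn{S(t)=1-\Phi((\log t-\mu)/\sigma)}.
#'
#' A positive hazard multiplier (`hr`) can be attached; for the Weibull and
#' exponential families it is folded into the rate in closed form, otherwise it
#' acts as a proportional-hazards transform \eqn{S(t)^{hr}}.
#'
#' @param family One of `"weibull"`, `"exponential"`, `"log_logistic"`,
#'   `"log_normal"`.
#' @param ... Named family parameters (see Details).
#' @return An object of class `parametric_survival`.
#' @examples
#' os <- parametric_survival("weibull", rate = 0.027, shape = 1.286)
#' survival_at(os, c(0, 12, 36))
#' median(os)
#' @export
parametric_survival <- function(family = c("weibull", "exponential",
                                           "log_logistic", "log_normal"),
                                ...) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    weibull = c("rate", "shape"),
    exponential = "rate",
    log_logistic = c("scale", "shape"),
    log_normal = c("meanlog", "sdlog"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop_hccea(sprintf("family '%s' requires parameters: %s",
                       family, paste(need, collapse = ", ")),
               class = "hccea_parameter_error")
  }
  params <- params[need]
  positive <- setdiff(need, "meanlog")  # meanlog is a log-scale location
  for (p in positive) {
    if (!is.finite(params[[p]]) || params[[p]] <= 0) {
      stop_hccea(sprintf("parameter '%s' must be strictly positive", p),
                 class = "hccea_parameter_error")
    }
  }
  if (family == "log_normal") check_number(params$meanlog, "meanlog")
  structure(list(family = family, params = params, hr = 1),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  pars <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                collapse = ", ")
  cat(sprintf("<parametric_survival> %s(%s)", x$family, pars))
  if (!isTRUE(all.equal(x$hr, 1))) cat(sprintf(" x HR %g", x$hr))
  cat("  [time in months]\n")
  invisible(x)
}

base_survival <- function(dist, t) {
  p <- dist$params
  switch(dist$family,
    weibull = exp(-p$rate * t^p$shape),
    exponential = exp(-p$rate * t),
    log_logistic = 1 / (1 + (t / p$scale)^p$shape),
    log_normal = ifelse(t == 0, 1, 1 - pnorm((log(pmax(t, .Machine$double.xmin)) -
                                                p$meanlog) / p$sdlog)))
}

#' Survivor function of a parametric law
#'
#' @param dist A [parametric_survival()] object.
#' @param t Time in months, `t >= 0` (vectorized).
#' @return Survival probabilities `S(t)`.
#' @examples
#' pfs <- parametric_survival("weibull", rate = 0.093, shape = 1.312)
#' survival_at(pfs, 4.62)  # ~0.5 at the median
#' @export
survival_at <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(t < 0)) {
    stop_hccea("time must be non-negative", class = "hccea_domain_error")
  }
  base_survival(dist, t)^dist$hr
}

#' Cumulative hazard of a parametric law
#'
#' @inheritParams survival_at
#' @return `H(t) = -log S(t)`.
#' @export
cumulative_hazard <- function(dist, t) -log(survival_at(dist, t))

#' Log density, used by the censored likelihood
#' @noRd
log_density <- function(dist, t) {
  # f = h * S; compute via numeric-stable closed forms including hr
  p <- dist$params
  hr <- dist$hr
  switch(dist$family,
    weibull = log(hr * p$rate * p$shape) + (p$shape - 1) * log(t) -
      hr * p$rate * t^p$shape,
    exponential = log(hr * p$rate) - hr * p$rate * t,
    {
      # general PH: f = hr * h0(t) * S0(t)^hr
      s0 <- base_survival(dist, t)
      h0 <- base_hazard(dist, t)
      log(hr) + log(h0) + hr * log(s0)
    })
}

base_hazard <- function(dist, t) {
  p <- dist$params
  switch(dist$family,
    weibull = p$rate * p$shape * t^(p$shape - 1),
    exponential = rep(p$rate, length(t)),
    log_logistic = {
      z <- (t / p$scale)^p$shape
      (p$shape / t) * z / (1 + z)
    },
    log_normal = {
      z <- (log(t) - p$meanlog) / p$sdlog
      stats::dnorm(z) / (p$sdlog * t) / (1 - pnorm(z))
    })
}

#' Hazard function of a parametric law
#'
#' @inheritParams survival_at
#' @return Instantaneous hazard `h(t)` (per month).
#' @export
hazard_at <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  dist$hr * base_hazard(dist, t)
}

#' Median survival time
#'
#' Closed form where available, otherwise numeric inversion.
#'
#' @param x A [parametric_survival()] object.
#' @param ... Unused.
#' @return Median time in months.
#' @export
median.parametric_survival <- function(x, ...) {
  p <- x$params
  target <- log(2) / x$hr  # S0(t) = exp(-log(2)/hr)  <=>  S0^hr = 1/2
  switch(x$family,
    weibull = (target / p$rate)^(1 / p$shape),
    exponential = target / p$rate,
    {
      f <- function(t) base_survival(x, t) - exp(-target)
      uniroot(f, c(1e-9, 1e6), tol = 1e-10)$root
    })
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of leaving the curve's at-risk population during
#' `[t, t + delta)` conditional on being event-free at `t`:
#' `1 - S(t + delta) / S(t)`. Returns 1 when `S(t)` has vanished (the state is
#' absorbed).
#'
#' @param dist A [parametric_survival()] object.
#' @param t Interval start, months (vectorized).
#' @param delta Interval length, months, `> 0`.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' os <- parametric_survival("weibull", rate = 0.027, shape = 1.286)
#' cycle_transition_prob(os, t = 0, delta = 21 / 365.25 * 12)
#' @export
cycle_transition_prob <- function(dist, t, delta) {
  check_number(delta, "delta", lower = .Machine$double.xmin)
  s0 <- survival_at(dist, t)
  s1 <- survival_at(dist, t + delta)
  out <- ifelse(s0 <= 0, 1, pmin(pmax(1 - s1 / s0, 0), 1))
  out
}

#' Apply a proportional hazard ratio
#'
#' Scales the hazard of a survival law by a constant factor. For Weibull and
#' exponential families the rate is rescaled in closed form (`rate -> hr *
#' rate`); for the log-logistic and log-normal families, which are not closed
#' under proportional hazards, the transform is carried as `S(t)^hr`.
#'
#' @param dist A [parametric_survival()] object.
#' @param hr Hazard ratio, `> 0`.
#' @return A new `parametric_survival` with hazard `hr * h(t)`.
#' @examples
#' sor <- parametric_survival("weibull", rate = 0.093, shape = 1.312)
#' ab <- apply_hazard_ratio(sor, 0.59)
#' median(ab)  # ~6.9 months
#' @export
apply_hazard_ratio <- function(dist, hr) {
  stopifnot(inherits(dist, "parametric_survival"))
  check_number(hr, "hr", lower = .Machine$double.xmin)
  if (dist$family %in% c("weibull", "exponential")) {
    out <- dist
    out$params$rate <- dist$params$rate * hr
    out
  } else {
    out <- dist
    out$hr <- dist$hr * hr
    out
  }
}

#' Random event times from a parametric law
#'
#' @param n Number of draws.
#' @param dist A [parametric_survival()] object.
#' @return Event times in months.
#' @export
rsurv <- function(n, dist) {
  stopifnot(inherits(dist, "parametric_survival"))
  p <- dist$params
  # inverse-CDF through the PH form: S0(t)^hr = U  =>  S0(t) = U^(1/hr)
  u <- runif(n)^(1 / dist$hr)
  switch(dist$family,
    weibull = (-log(u) / p$rate)^(1 / p$shape),
    exponential = -log(u) / p$rate,
    log_logistic = p$scale * ((1 - u) / u)^(1 / p$shape),
    log_normal = exp(p$meanlog + p$sdlog * qnorm(1 - u)))
}
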