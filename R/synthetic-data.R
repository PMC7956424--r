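#' Simulate a right-censored survival cohort
#'
#' Draws event times from a parametric survival law, with independent
#' exponential censoring and administrative censoring at the end of follow-up.
#' The observed time is the minimum of the three; the event indicator is 1
#' only when the event time is that minimum. Used to exercise curve
#' reconstruction and parametric fitting with known truth.
#'
#' @param dist A [parametric_survival()] generating law.
#' @param n Number of subjects, `>= 1`.
#' @param censor_rate Exponential censoring rate per month, `>= 0`
#'   (0 disables random censoring).
#' @param max_follow_up Administrative censoring time in months, `> 0`
#'   (may be `Inf`).
#' @param seed Integer seed; the cohort is reproducible bit-for-bit.
#' @return A tibble with columns `time` (months) and `event` (0/1), carrying
#'   the generating law in attribute `"truth"` and the seed in `"seed"`.
#' @examples
#' os <- parametric_survival("weibull", rate = 0.027, shape = 1.286)
#' cohort <- simulate_survival(os, n = 200, censor_rate = 0.02,
#'                             max_follow_up = 60, seed = 1)
#' mean(cohort$event)
#' @export
simulate_survival <- function(dist, n, censor_rate = 0, max_follow_up = Inf,
                              seed = 1L) {
  stopifnot(inherits(dist, "parametric_survival"))
  check_number(n, "n", lower = 1)
  check_number(censor_rate, "censor_rate", lower = 0)
  check_number(max_follow_up, "max_follow_up",
               lower = .Machine$double.xmin, finite = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  event_time <- rsurv(n, dist)
  censor_time <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  time <- pmin(event_time, censor_time, max_follow_up)
  event <- as.integer(event_time <= pmin(censor_time, max_follow_up))
  out <- tibble(time = time, event = event)
  attr(out, "truth") <- dist
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("hccea_cohort", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Kaplan-Meier estimate on a grid
#'
#' Product-limit estimator evaluated as a right-continuous step function on an
#' arbitrary time grid.
#'
#' @param ipd A data frame with columns `time` and `event` (0/1).
#' @param grid Ascending evaluation times in months.
#' @return A tibble with columns `time` and `survival`.
#' @examples
#' km_estimate(tibble::tibble(time = 1:3, event = 1), grid = c(0, 2.5))
#' @export
km_estimate <- function(ipd, grid) {
  ipd <- validate_ipd(ipd)
  if (is.unsorted(grid)) {
    stop_hccea("grid must be ascending", class = "hccea_input_error")
  }
  fit <- km_steps(ipd$time, ipd$event)
  if (length(fit$time) == 0) {
    return(tibble(time = as.numeric(grid), survival = rep(1, length(grid))))
  }
  surv <- stats::stepfun(fit$time, c(1, fit$survival), right = FALSE)
  tibble(time = as.numeric(grid), survival = surv(grid))
}

# distinct event times, at-risk counts, KM survival after each event time
km_steps <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  ev_times <- unique(time[event == 1])
  n <- length(time)
  s <- 1
  out_s <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    tt <- ev_times[i]
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
    out_s[i] <- s
  }
  list(time = ev_times, survival = out_s)
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop_hccea("ipd must be a data frame with columns `time` and `event`",
               class = "hccea_input_error")
  }
  if (nrow(ipd) == 0) {
    stop_hccea("ipd is empty", class = "hccea_input_error")
  }
  if (any(ipd$time <= 0)) {
    stop_hccea("times must be strictly positive", class = "hccea_input_error")
  }
  if (!all(ipd$event %in% c(0, 1))) {
    stop_hccea("event must be 0/1", class = "hccea_input_error")
  }
  ipd
}

#' Digitized-style Kaplan-Meier curve from a cohort
#'
#' Computes the KM estimate of a simulated cohort on a coordinate grid and
#' tabulates true numbers at risk, emulating the output of manual curve
#' digitization. Optional multiplicative log-normal jitter mimics digitization
#' error; jittered values are clamped to `[0, 1]` and forced monotone
#' non-increasing so the result remains a valid survival curve.
#'
#' @param cohort A data frame with `time` and `event` columns.
#' @param coordinate_grid Ascending times (months) starting at 0 at which the
#'   curve is read off.
#' @param risk_table_times Ascending times (months) starting at 0 for the
#'   numbers-at-risk table.
#' @param jitter Relative (log-normal sigma) noise magnitude; 0 for none.
#' @param seed Integer seed for the jitter.
#' @return A [km_curve()] object.
#' @export
make_km_curve <- function(cohort, coordinate_grid, risk_table_times,
                          jitter = 0, seed = 1L) {
  cohort <- validate_ipd(cohort)
  for (g in list(coordinate_grid, risk_table_times)) {
    if (length(g) < 2 || is.unsorted(g, strictly = TRUE) || g[1] != 0) {
      stop_hccea("grids must be strictly ascending and start at 0",
                 class = "hccea_input_error")
    }
  }
  est <- km_estimate(cohort, coordinate_grid)
  surv <- est$survival
  if (jitter > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    noisy <- surv * rlnorm(length(surv), 0, jitter)
    noisy[1] <- 1
    noisy <- pmin(pmax(noisy, 0), 1)
    surv <- cummin(noisy)  # repair monotonicity
  }
  n_at_risk <- vapply(risk_table_times,
                      function(tt) sum(cohort$time >= tt), integer(1))
  km_curve(coords = tibble(time = as.numeric(coordinate_grid), survival = surv),
           risk_table = tibble(time = as.numeric(risk_table_times),
                               n_risk = n_at_risk),
           n0 = nrow(cohort))
}

#' Synthetic Gompertz-style life table
#'
#' Annual mortality probability doubling at a fixed age interval, capped at 1.
#' A coarse stand-in for a national life table with the same `(age, qx)`
#' interface; defaults approximate contemporary US all-cause mortality
#' (`qx(65)` near 0.015, `qx(80)` near 0.05).
#'
#' @param base_rate Annual death probability at age 18, in `(0, 1)`.
#' @param doubling_time Years over which the probability doubles, `> 0`.
#' @param ages Integer ages covered (must span at least 18-100).
#' @return A tibble with columns `age` and `qx`.
#' @examples
#' lt <- make_life_table(0.001, 8)
#' lt$qx[lt$age == 26]  # one doubling: 0.002
#' @export
make_life_table <- function(base_rate = 4e-4, doubling_time = 9,
                            ages = 18:110) {
  check_number(base_rate, "base_rate", lower = 1e-12, upper = 1 - 1e-12)
  check_number(doubling_time, "doubling_time", lower = .Machine$double.xmin)
  ages <- as.integer(ages)
  if (is.unsorted(ages, strictly = TRUE) || min(ages) > 18 || max(ages) < 100) {
    stop_hccea("ages must be strictly increasing and cover 18-100",
               class = "hccea_input_error")
  }
  tibble(age = ages,
         qx = pmin(base_rate * 2^((ages - 18) / doubling_time), 1))
}

validate_life_table <- function(life_table) {
  if (!is.data.frame(life_table) ||
      !all(c("age", "qx") %in% names(life_table))) {
    stop_hccea("life table needs columns `age` and `qx`",
               class = "hccea_input_error")
  }
  if (is.unsorted(life_table$age, strictly = TRUE) ||
      any(life_table$qx < 0 | life_table$qx > 1)) {
    stop_hccea("life table ages must increase and qx lie in [0, 1]",
               class = "hccea_input_error")
  }
  life_table
}

# annual probability -> monthly hazard at (possibly fractional) ages
background_hazard_monthly <- function(life_table, age) {
  lt <- validate_life_table(life_table)
  idx <- findInterval(floor(age), lt$age)
  if (any(idx == 0) || any(floor(age) > max(lt$age))) {
    stop_hccea("life table does not cover the required ages",
               class = "hccea_range_error")
  }
  -log(1 - pmin(lt$qx[idx], 1 - 1e-12)) / 12
}

#' Write / read delimiter-separated exports
#'
#' Cohorts export as `(time, event)`, life tables as `(age, qx)`; both round
#' trip through plain CSV.
#'
#' @param x A cohort or life table tibble.
#' @param path File path.
#' @return `x`, invisibly (writers); a tibble (readers).
#' @name hccea_io
#' @export
write_cohort <- function(x, path) {
  validate_ipd(x)
  readr::write_csv(x[c("time", "event")], path)
  invisible(x)
}

#' @rdname hccea_io
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  validate_ipd(out)
}

#' @rdname hccea_io
#' @export
write_life_table <- function(x, path) {
  validate_life_table(x)
  readr::write_csv(x[c("age", "qx")], path)
  invisible(x)
}

#' @rdname hccea_io
#' @export
read_life_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  validate_life_table(out)
}
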