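#' Digitized Kaplan-Meier curve container
#'
#' Holds digitized survival coordinates, a numbers-at-risk table, and the
#' initial cohort size, validated against the basic KM shape constraints.
#' Small monotonicity violations from digitization error (up to `repair`) are
#' repaired by a running minimum and reported via a message; larger rises are
#' rejected.
#'
#' @param coords Data frame with ascending `time` (months) and `survival`;
#'   first row must be `(0, 1)`.
#' @param risk_table Data frame with ascending `time` and non-increasing
#'   `n_risk` counts; first count is the cohort size unless `n0` is given.
#' @param n0 Initial cohort size (defaults to the first risk-table count).
#' @param repair Maximum survival rise treated as digitization noise (default
#'   0.005).
#' @return An object of class `km_curve`.
#' @export
km_curve <- function(coords, risk_table, n0 = NULL, repair = 0.005) {
  coords <- as_tibble(coords)
  risk_table <- as_tibble(risk_table)
  if (!all(c("time", "survival") %in% names(coords)) ||
      !all(c("time", "n_risk") %in% names(risk_table))) {
    stop_hccea("coords need `time`,`survival`; risk_table needs `time`,`n_risk`",
               class = "hccea_validation_error")
  }
  if (nrow(coords) < 2 || coords$time[1] != 0 ||
      abs(coords$survival[1] - 1) > 1e-9) {
    stop_hccea("coordinates must start at (0, 1)",
               class = "hccea_validation_error")
  }
  if (is.unsorted(coords$time, strictly = TRUE)) {
    stop_hccea("coordinate times must be strictly ascending",
               class = "hccea_validation_error")
  }
  if (any(coords$survival < -1e-9 | coords$survival > 1 + 1e-9)) {
    stop_hccea("survival values must lie in [0, 1]",
               class = "hccea_validation_error")
  }
  rises <- diff(coords$survival)
  if (any(rises > repair)) {
    k <- which(rises > repair)[1]
    stop_hccea(sprintf(
      "survival rises by %.4f between t = %.3f and t = %.3f",
      rises[k], coords$time[k], coords$time[k + 1]),
      class = "hccea_validation_error")
  }
  if (any(rises > 0)) {
    message("km_curve: repaired ", sum(rises > 0),
            " small monotonicity violation(s) by running minimum")
    coords$survival <- cummin(coords$survival)
  }
  if (nrow(risk_table) < 2 || is.unsorted(risk_table$time)) {
    stop_hccea("risk table needs >= 2 ascending times",
               class = "hccea_validation_error")
  }
  if (any(diff(risk_table$n_risk) > 0)) {
    k <- which(diff(risk_table$n_risk) > 0)[1]
    stop_hccea(sprintf("numbers at risk increase between t = %.3f and t = %.3f",
                       risk_table$time[k], risk_table$time[k + 1]),
               class = "hccea_validation_error")
  }
  n0 <- n0 %||% risk_table$n_risk[1]
  if (any(risk_table$n_risk > n0)) {
    stop_hccea("risk-table counts exceed the initial cohort size",
               class = "hccea_validation_error")
  }
  structure(list(coords = coords, risk_table = risk_table, n0 = as.integer(n0)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d coordinates over %.1f months, n0 = %d, %d risk-table rows\n",
              nrow(x$coords), max(x$coords$time), x$n0, nrow(x$risk_table)))
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Interval-wise iterative allocation of event and censoring counts in the
#' Guyot family of algorithms: within each interval between adjacent
#' numbers-at-risk times, censorings are spread uniformly and their total is
#' adjusted until the implied number at risk at the next risk-table time
#' matches the published count; event counts at each digitized coordinate are
#' chosen so the running product-limit estimate tracks the digitized survival
#' as closely as integer counts allow. After the last risk-table time the
#' censoring rate of the preceding intervals is carried forward (or the known
#' total event count, when supplied, pins the allocation).
#'
#' @param curve A [km_curve()] object.
#' @param total_events Optional known total number of events; when supplied,
#'   event allocation beyond the last risk-table time is rescaled so the total
#'   matches.
#' @return A tibble of `n0` rows with columns `time` and `event`.
#' @examples
#' os <- parametric_survival("weibull", rate = 0.027, shape = 1.286)
#' cohort <- simulate_survival(os, 300, censor_rate = 0.015,
#'                             max_follow_up = 30, seed = 7)
#' curve <- make_km_curve(cohort, seq(0, 30, by = 0.5), seq(0, 30, by = 6))
#' ipd <- reconstruct_ipd(curve)
#' nrow(ipd) == 300
#' @export
reconstruct_ipd <- function(curve, total_events = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  co <- curve$coords
  rt <- curve$risk_table
  if (nrow(rt) < 2) {
    stop_hccea("risk table needs at least 2 entries",
               class = "hccea_validation_error")
  }
  K <- nrow(co)
  # interval boundaries: risk-table times, extended past the last coordinate
  bounds <- c(rt$time, max(co$time) + 1e-9)
  J <- length(bounds) - 1
  ev_time <- numeric(0); ev_n <- integer(0)
  cn_time <- numeric(0)
  n_cur <- curve$n0
  s_km <- 1
  cens_seen <- 0L; time_seen <- 0
  for (j in seq_len(J)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    idx <- which(co$time >= lo & co$time < hi & co$time > 0)
    last_interval <- j > nrow(rt) - 1
    target_n <- if (!last_interval) rt$n_risk[j + 1] else NA_integer_
    if (!last_interval) {
      c_guess <- max(0L, n_cur - target_n -
                       sum_events_guess(co, idx, n_cur, s_km))
    } else {
      # carry forward the observed censoring intensity (per month)
      rate <- if (time_seen > 0) cens_seen / time_seen else 0
      c_guess <- min(n_cur, as.integer(round(rate * (hi - lo))))
    }
    best <- NULL
    for (iter in 1:60) {
      c_guess <- max(0L, min(n_cur, as.integer(c_guess)))
      alloc <- allocate_interval(co, idx, lo, hi, n_cur, s_km, c_guess)
      if (last_interval) { best <- alloc; break }
      gap <- alloc$n_end - target_n
      if (abs(gap) == 0) { best <- alloc; break }
      best <- alloc
      c_new <- c_guess + gap
      if (c_new == c_guess) break
      c_guess <- c_new
    }
    ev_time <- c(ev_time, best$ev_time); ev_n <- c(ev_n, best$ev_n)
    cn_time <- c(cn_time, best$cn_time)
    cens_seen <- cens_seen + length(best$cn_time)
    time_seen <- time_seen + (hi - lo)
    n_cur <- best$n_end
    s_km <- best$s_km
  }
  # survivors at the end of the digitized range are censored there
  times <- c(rep(ev_time, ev_n), cn_time, rep(max(co$time), n_cur))
  events <- c(rep(1L, sum(ev_n)), rep(0L, length(cn_time) + n_cur))
  out <- tibble(time = times, event = events) %>% arrange(.data$time)
  if (!is.null(total_events) && sum(out$event) != total_events) {
    out <- rescale_events(out, total_events)
  }
  stopifnot(nrow(out) == curve$n0)
  out
}

# quick event-count estimate for the initial censoring guess
sum_events_guess <- function(co, idx, n_cur, s_km) {
  if (!length(idx) || s_km <= 0) return(0L)
  s_end <- co$survival[max(idx)]
  as.integer(round(n_cur * (1 - s_end / s_km)))
}

# walk the coordinates of one interval with c_cens censorings spread uniformly
allocate_interval <- function(co, idx, lo, hi, n_cur, s_km, c_cens) {
  cn_time <- if (c_cens > 0) lo + (seq_len(c_cens) - 0.5) / c_cens * (hi - lo)
             else numeric(0)
  used_cens <- 0L
  ev_time <- numeric(0); ev_n <- integer(0)
  for (k in idx) {
    tk <- co$time[k]
    # censorings occurring before this coordinate leave the risk set first
    due <- sum(cn_time <= tk) - used_cens
    take <- min(due, n_cur)
    n_cur <- n_cur - take
    used_cens <- used_cens + take
    if (n_cur <= 0 || s_km <= 0) next
    d <- round(n_cur * (1 - co$survival[k] / s_km))
    d <- max(0L, min(as.integer(d), n_cur))
    if (d > 0) {
      s_km <- s_km * (1 - d / n_cur)
      n_cur <- n_cur - d
      ev_time <- c(ev_time, tk); ev_n <- c(ev_n, d)
    }
  }
  due <- length(cn_time) - used_cens
  take <- min(due, n_cur)
  n_cur <- n_cur - take
  used_cens <- used_cens + take
  list(ev_time = ev_time, ev_n = ev_n,
       cn_time = cn_time[seq_len(used_cens)],
       n_end = n_cur, s_km = s_km)
}

# flip the latest events to censorings (or earliest censorings to events)
# until the total event count matches a known external total
rescale_events <- function(out, total_events) {
  diffn <- sum(out$event) - total_events
  if (diffn > 0) {
    flip <- utils::tail(which(out$event == 1L), diffn)
    out$event[flip] <- 0L
  } else if (diffn < 0) {
    flip <- utils::head(which(out$event == 0L), -diffn)
    out$event[flip] <- 1L
  }
  out
}
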