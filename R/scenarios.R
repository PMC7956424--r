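#' Long-term survival scenario
#'
#' The trial reports survival over roughly 17 months of follow-up; what
#' happens afterwards is a modelling choice. Three modes are supported for
#' the arm the scenario applies to:
#'
#' * `extrapolate` (base case): the fitted overall-survival law continues
#'   unchanged past the switch time.
#' * `optimistic`: survivors at the switch time are considered cured —
#'   their death hazard falls to age-adjusted background mortality, further
#'   progression stops, and (by default) anti-cancer therapy costs stop,
#'   while surveillance continues. See `cure_stops_therapy` /
#'   `cure_stops_progression`.
#' * `pessimistic`: after the switch a constant excess hazard is added to
#'   background mortality, calibrated so the modelled survival at
#'   `anchor_time` equals `anchor` (a registry-based landmark).
#'
#' All three leave the survival function continuous at the switch.
#'
#' @param mode `"extrapolate"`, `"pessimistic"` or `"optimistic"`.
#' @param switch_time Months after which the long-term assumption applies
#'   (base 17).
#' @param anchor Survival probability at `anchor_time` used to calibrate the
#'   pessimistic mode (printed registry landmarks: 0.278, alternatively
#'   0.238).
#' @param anchor_time Months at which the anchor applies (base 36).
#' @param applies_to Name of the strategy the scenario modifies (the
#'   comparator keeps plain extrapolation).
#' @param cure_stops_therapy In optimistic mode, stop drug, administration
#'   and post-progression therapy costs at the switch (default `TRUE`);
#'   imaging and other care continue while alive.
#' @param cure_stops_progression In optimistic mode, stop further
#'   progression at the switch (default `TRUE`).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(mode = c("extrapolate", "pessimistic", "optimistic"),
                          switch_time = 17, anchor = 0.278, anchor_time = 36,
                          applies_to = "atezolizumab-bevacizumab",
                          cure_stops_therapy = TRUE,
                          cure_stops_progression = TRUE) {
  mode <- match.arg(mode)
  check_number(switch_time, "switch_time", lower = 1e-9)
  check_number(anchor, "anchor", lower = 1e-9, upper = 1 - 1e-9)
  check_number(anchor_time, "anchor_time", lower = switch_time)
  structure(list(mode = mode, switch_time = switch_time, anchor = anchor,
                 anchor_time = anchor_time, applies_to = applies_to,
                 cure_stops_therapy = isTRUE(cure_stops_therapy),
                 cure_stops_progression = isTRUE(cure_stops_progression)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s (switch %.0f mo%s) for %s\n", x$mode,
              x$switch_time,
              if (x$mode == "pessimistic")
                sprintf(", anchor S(%.0f) = %.3f", x$anchor_time, x$anchor)
              else "",
              x$applies_to))
  invisible(x)
}

#' Calibrate the pessimistic excess hazard
#'
#' Constant monthly excess hazard `h` such that the model's all-cause
#' survival at the anchor time equals the anchor:
#' `S(switch) * exp(-Hbg(0, T) - h * (T - switch)) = anchor`, where `Hbg` is
#' the cumulative background hazard accrued since model entry at `start_age`
#' (background mortality acts additively on the fitted disease curve
#' throughout). Closed form; a negative value (anchor above the extrapolated
#' tail) is allowed with a warning so the calibration always reproduces the
#' anchor exactly.
#'
#' @param base_os A [parametric_survival()] law.
#' @param scenario A [scenario_spec()] in pessimistic mode.
#' @param life_table Life table tibble (`age`, `qx`).
#' @param start_age Cohort entry age in years.
#' @return Monthly excess hazard (numeric scalar).
#' @export
calibrate_excess_hazard <- function(base_os, scenario, life_table,
                                    start_age = 65) {
  s_sw <- survival_at(base_os, scenario$switch_time)
  if (scenario$anchor >= s_sw) {
    stop_hccea(sprintf(
      "anchor %.3f is not attainable: survival at the switch time is %.3f",
      scenario$anchor, s_sw), class = "hccea_calibration_error")
  }
  hbg <- integrate_bg_hazard(life_table, start_age, 0, scenario$anchor_time)
  h <- (log(s_sw / scenario$anchor) - hbg) /
    (scenario$anchor_time - scenario$switch_time)
  if (h < 0) {
    warning("calibrated excess hazard is negative: the anchor lies above ",
            "the extrapolated survival curve", call. = FALSE)
  }
  h
}

# cumulative monthly background hazard between two model times (months)
integrate_bg_hazard <- function(life_table, start_age, from, to) {
  if (to <= from) return(0)
  grid <- seq(from, to, by = 0.25)
  h <- background_hazard_monthly(life_table, start_age + grid / 12)
  sum((h[-1] + h[-length(h)]) / 2 * diff(grid))
}

#' Piecewise long-term death hazard
#'
#' Total monthly death hazard (disease plus background) as a function of time
#' under a long-term scenario. Before the switch time the fitted law's hazard
#' applies; after it, the scenario mode decides: `extrapolate` keeps the
#' fitted hazard, `optimistic` leaves background mortality only, and
#' `pessimistic` adds the calibrated constant excess hazard to background
#' mortality. The implied survival function is continuous at the switch.
#'
#' @inheritParams calibrate_excess_hazard
#' @return A function `h(t)` of time in months returning the monthly hazard.
#' @examples
#' lt <- make_life_table()
#' os <- apply_hazard_ratio(
#'   parametric_survival("weibull", rate = 0.027, shape = 1.286), 0.58)
#' h <- longterm_hazard(os, scenario_spec("optimistic"), lt, 65)
#' h(c(10, 20))
#' @export
longterm_hazard <- function(base_os, scenario, life_table, start_age = 65) {
  stopifnot(inherits(scenario, "scenario_spec"))
  h_ex <- if (scenario$mode == "pessimistic") {
    calibrate_excess_hazard(base_os, scenario, life_table, start_age)
  } else 0
  function(t) {
    hbg <- background_hazard_monthly(life_table, start_age + t / 12)
    before <- t < scenario$switch_time
    h_dis <- numeric(length(t))
    h_dis[before] <- hazard_at(base_os, pmax(t[before], 1e-9))
    if (any(!before)) {
      h_dis[!before] <- switch(scenario$mode,
        extrapolate = hazard_at(base_os, t[!before]),
        optimistic = 0,
        pessimistic = h_ex)
    }
    pmax(h_dis + hbg, 0)
  }
}
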