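#' Per-cycle transition probabilities
#'
#' Builds the cycle-by-cycle transition structure of the three-state model
#' (progression-free, progressed, dead). The death probability — shared by
#' both alive states — combines the (scenario-modified) overall-survival
#' hazard of the cycle with the age-specific background hazard on the hazard
#' scale before conversion to a probability; the progression-free-exit
#' probability comes from the PFS law the same way, and the progression
#' probability is the non-negative difference.
#'
#' @param strategy A [strategy_spec()].
#' @param settings A [model_settings()].
#' @param life_table Life table tibble (`age`, `qx`) covering the horizon.
#' @param scenario Optional [scenario_spec()]; applied only when its
#'   `applies_to` matches the strategy name.
#' @return A tibble with one row per cycle: `cycle`, `t0`, `t1` (months),
#'   `p_death`, `p_prog`, `p_exit`, `cured`, `therapy_off`, plus a
#'   `"settings"` attribute. Use [as_transition_array()] for explicit 3x3
#'   matrices.
#' @export
build_transitions <- function(strategy, settings, life_table,
                              scenario = NULL) {
  stopifnot(inherits(strategy, "strategy_spec"),
            inherits(settings, "model_settings"))
  life_table <- validate_life_table(life_table)
  applies <- !is.null(scenario) &&
    identical(scenario$applies_to, strategy$name)
  if (applies) stopifnot(inherits(scenario, "scenario_spec"))
  dm <- settings$cycle_months
  k <- seq_len(settings$n_cycles)
  t0 <- (k - 1) * dm
  t1 <- k * dm
  mid <- (t0 + t1) / 2
  h_bg <- background_hazard_monthly(life_table, settings$start_age + mid / 12)

  mode <- if (applies) scenario$mode else "extrapolate"
  sw <- if (applies) scenario$switch_time else Inf
  post <- t0 >= sw
  h_ex <- if (mode == "pessimistic") {
    calibrate_excess_hazard(strategy$os_model, scenario, life_table,
                            settings$start_age)
  } else 0

  # disease death hazard per month, averaged over the cycle
  h_os <- -log(pmax(1 - cycle_transition_prob(strategy$os_model, t0, dm),
                    .Machine$double.xmin)) / dm
  h_os[post] <- switch(mode, extrapolate = h_os[post], optimistic = 0,
                       pessimistic = h_ex)
  h_pfs <- -log(pmax(1 - cycle_transition_prob(strategy$pfs_model, t0, dm),
                     .Machine$double.xmin)) / dm
  cured <- post & mode == "optimistic"
  if (any(cured) && scenario$cure_stops_progression) h_pfs[cured] <- 0

  p_death <- 1 - exp(-(h_os + h_bg) * dm)
  p_exit <- 1 - exp(-(h_pfs + h_bg) * dm)
  p_prog <- pmax(0, p_exit - p_death)
  out <- tibble(cycle = k, t0 = t0, t1 = t1,
                p_death = p_death, p_prog = p_prog, p_exit = p_exit,
                cured = cured,
                therapy_off = cured &
                  (if (applies) scenario$cure_stops_therapy else FALSE))
  attr(out, "settings") <- settings
  class(out) <- c("hccea_transitions", class(out))
  out
}

#' Explicit per-cycle 3x3 transition matrices
#'
#' @param transitions Output of [build_transitions()].
#' @return An array `[cycle, from, to]` over states `pf`, `pd`, `dead`; each
#'   row sums to 1 and `dead` is absorbing.
#' @export
as_transition_array <- function(transitions) {
  states <- c("pf", "pd", "dead")
  n <- nrow(transitions)
  arr <- array(0, dim = c(n, 3, 3), dimnames = list(NULL, states, states))
  arr[, "pf", "pf"] <- 1 - transitions$p_death - transitions$p_prog
  arr[, "pf", "pd"] <- transitions$p_prog
  arr[, "pf", "dead"] <- transitions$p_death
  arr[, "pd", "pd"] <- 1 - transitions$p_death
  arr[, "pd", "dead"] <- transitions$p_death
  arr[, "dead", "dead"] <- 1
  arr
}

#' Run the Markov cohort model for one strategy
#'
#' The cohort starts fully progression-free. Per-cycle accruals use the mean
#' of start- and end-of-cycle occupancy (half-cycle correction, optional) and
#' are discounted at the cycle midpoint. Costs: drug and administration on
#' the time-on-treatment occupancy of each drug component (exponential curve
#' at the trial's median duration times the alive fraction, stopped by a
#' duration cap or by cure); imaging and other care while alive;
#' post-progression therapy per cycle in the progressed state (stopped by
#' cure); a one-off end-of-life cost on the transition to death; and the
#' adverse-event burden once at model entry. QALYs weight occupancy by the
#' state utilities; the AE disutility is a one-off decrement at entry.
#'
#' @param strategy A [strategy_spec()].
#' @param settings A [model_settings()].
#' @param transitions Output of [build_transitions()] for this strategy.
#' @return An object of class `cohort_result`: list with `trace` (per-cycle
#'   tibble) and `outcome` (one-row tibble with discounted `total_cost`,
#'   `qalys`, `life_years` and their undiscounted counterparts).
#' @examples
#' lt <- make_life_table()
#' st <- model_settings()
#' sor <- sorafenib_strategy()
#' res <- run_cohort(sor, st, build_transitions(sor, st, lt))
#' glance(res)
#' @export
run_cohort <- function(strategy, settings, transitions) {
  stopifnot(inherits(strategy, "strategy_spec"),
            inherits(settings, "model_settings"))
  if (nrow(transitions) < settings$n_cycles) {
    stop_hccea("transitions do not cover all cycles",
               class = "hccea_input_error")
  }
  dm <- settings$cycle_months
  dy <- dm / 12
  sc <- settings$cycle_length_days / 21  # costs are priced per 3-week cycle
  hcc <- settings$half_cycle_correction
  ae <- ae_burden(strategy)
  soc <- strategy$societal
  soc_on <- !is.null(soc) && isTRUE(soc$active)

  dur_rates <- log(2) / strategy$drug_components$duration_median
  comp_costs <- strategy$drug_components$cost_per_cycle *
    strategy$price_multiplier
  admin_comp <- which.max(strategy$drug_components$duration_median)

  pf <- 1; pd <- 0; dead <- 0
  n <- settings$n_cycles
  trace <- vector("list", n)
  tot <- c(cost = ae$ae_cost, cost_undisc = ae$ae_cost,
           qaly = -ae$ae_disutility, qaly_undisc = -ae$ae_disutility,
           ly = 0, ly_undisc = 0)
  for (i in seq_len(n)) {
    tr <- transitions[i, ]
    pf2 <- pf * (1 - tr$p_death - tr$p_prog)
    pd2 <- pd * (1 - tr$p_death) + pf * tr$p_prog
    dead2 <- 1 - pf2 - pd2
    mpf <- if (hcc) (pf + pf2) / 2 else pf
    mpd <- if (hcc) (pd + pd2) / 2 else pd
    alive <- mpf + mpd
    mid <- (tr$t0 + tr$t1) / 2
    df <- (1 + settings$discount_rate)^(-mid / 12)

    on_trt <- if (tr$therapy_off || mid >= strategy$duration_cap) {
      rep(0, length(dur_rates))
    } else {
      exp(-dur_rates * mid) * alive
    }
    drug_cost <- sum(on_trt * comp_costs) * sc
    admin_cost <- on_trt[admin_comp] * strategy$admin_cost * sc
    care_cost <- alive * (strategy$imaging_cost_6wk / 2 +
                            strategy$other_care_weekly * 3) * sc
    pp_cost <- if (tr$therapy_off) 0 else
      mpd * strategy$post_progression_cost * sc
    eol_cost <- (dead2 - dead) * strategy$eol_cost
    cost <- drug_cost + admin_cost + care_cost + pp_cost + eol_cost
    if (soc_on) {
      cost <- cost + alive * soc$caregiver_cycle * sc +
        on_trt[admin_comp] * (soc$patient_time + soc$travel) * sc
    }
    if (cost < -1e-9) {
      stop_hccea("negative cost accrual", class = "hccea_internal_error")
    }
    qaly <- (mpf * strategy$utility_pf + mpd * strategy$utility_pd) * dy
    ly <- alive * dy

    tot <- tot + c(cost * df, cost, qaly * df, qaly, ly * df, ly)
    trace[[i]] <- tibble(cycle = tr$cycle, t0 = tr$t0, t1 = tr$t1,
                         pf = pf2, pd = pd2, dead = dead2,
                         cost = cost, cost_disc = cost * df,
                         qaly = qaly, qaly_disc = qaly * df,
                         ly = ly, ly_disc = ly * df)
    pf <- pf2; pd <- pd2; dead <- dead2
  }
  outcome <- tibble(strategy = strategy$name,
                    total_cost = tot[["cost"]],
                    qalys = tot[["qaly"]],
                    life_years = tot[["ly"]],
                    total_cost_undisc = tot[["cost_undisc"]],
                    qalys_undisc = tot[["qaly_undisc"]],
                    life_years_undisc = tot[["ly_undisc"]])
  structure(list(trace = dplyr::bind_rows(trace), outcome = outcome,
                 strategy = strategy$name),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("<cohort_result> %s: cost %.0f USD, %.3f QALYs, %.3f LY (discounted)\n",
              o$strategy, o$total_cost, o$qalys, o$life_years))
  invisible(x)
}

#' @rdname run_cohort
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @method tidy cohort_result
#' @export
tidy.cohort_result <- function(x, ...) x$trace

#' @rdname run_cohort
#' @method glance cohort_result
#' @export
glance.cohort_result <- function(x, ...) x$outcome

#' Build transitions and run the cohort in one call
#'
#' @inheritParams build_transitions
#' @return A `cohort_result`.
#' @export
run_strategy <- function(strategy, settings, life_table, scenario = NULL) {
  run_cohort(strategy, settings,
             build_transitions(strategy, settings, life_table, scenario))
}

outcome_row <- function(x) {
  if (inherits(x, "cohort_result")) return(x$outcome)
  stopifnot(is.data.frame(x), nrow(x) == 1,
            all(c("total_cost", "qalys", "life_years") %in% names(x)))
  x
}

#' Incremental cost-effectiveness comparison
#'
#' Differences are `a - b`. The ICER is the incremental cost per incremental
#' QALY (and per life-year); when the signs make a ratio meaningless a
#' dominance label replaces it (`"dominant"` = cheaper and more effective,
#' `"dominated"` = dearer and less effective). Net monetary benefit is
#' `wtp * delta_qalys - delta_cost` for each threshold.
#'
#' @param a,b `cohort_result` objects (or one-row outcome tibbles);
#'   `a` is the intervention, `b` the comparator.
#' @param wtps Willingness-to-pay thresholds, USD/QALY.
#' @return A one-row tibble: `delta_cost`, `delta_qalys`, `delta_life_years`,
#'   `icer_qaly`, `icer_ly`, `label`, and one `nmb_<wtp>` column per
#'   threshold.
#' @export
compare <- function(a, b, wtps = c(1e5, 1.5e5)) {
  oa <- outcome_row(a); ob <- outcome_row(b)
  d_cost <- oa$total_cost - ob$total_cost
  d_q <- oa$qalys - ob$qalys
  d_ly <- oa$life_years - ob$life_years
  label <- if (d_q > 0 && d_cost <= 0) "dominant"
           else if (d_q < 0 && d_cost >= 0) "dominated"
           else if (d_q == 0) if (d_cost == 0) "equivalent" else "no effect difference"
           else "icer"
  icer_q <- if (label == "icer") d_cost / d_q else NA_real_
  icer_l <- if (label == "icer" && d_ly > 0) d_cost / d_ly else NA_real_
  out <- tibble(delta_cost = d_cost, delta_qalys = d_q,
                delta_life_years = d_ly, icer_qaly = icer_q,
                icer_ly = icer_l, label = label)
  for (w in wtps) out[[paste0("nmb_", format(w, scientific = FALSE))]] <-
    w * d_q - d_cost
  out
}
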