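#' Model settings
#'
#' Cycle structure, horizon, discounting and willingness-to-pay thresholds of
#' the Markov cohort model.
#'
#' @param cycle_length_days Cycle length in days (21 = 3 weeks).
#' @param horizon_years Time horizon in years (base 5).
#' @param discount_rate Annual discount rate for both costs and outcomes
#'   (base 0.03).
#' @param start_age Cohort age at model entry, used for background mortality.
#' @param wtp_thresholds Willingness-to-pay thresholds, USD per QALY.
#' @param half_cycle_correction Count state membership as the mean of start-
#'   and end-of-cycle occupancy (default `TRUE`).
#' @return A `model_settings` list; `n_cycles` is
#'   `floor(horizon_years * 365.25 / cycle_length_days)`.
#' @examples
#' model_settings()$n_cycles  # 86 three-week cycles in 5 years
#' @export
model_settings <- function(cycle_length_days = 21, horizon_years = 5,
                           discount_rate = 0.03, start_age = 65,
                           wtp_thresholds = c(1e5, 1.5e5),
                           half_cycle_correction = TRUE) {
  check_number(cycle_length_days, "cycle_length_days", lower = 1)
  check_number(horizon_years, "horizon_years", lower = 1e-6)
  check_number(discount_rate, "discount_rate", lower = 0, upper = 1 - 1e-9)
  check_number(start_age, "start_age", lower = 18, upper = 100)
  structure(list(cycle_length_days = cycle_length_days,
                 cycle_months = cycle_months(cycle_length_days),
                 horizon_years = horizon_years,
                 n_cycles = as.integer(floor(horizon_years * 365.25 /
                                               cycle_length_days)),
                 discount_rate = discount_rate,
                 start_age = start_age,
                 wtp_thresholds = wtp_thresholds,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

#' Bevacizumab cost per cycle
#'
#' Linear scaling of the 70 kg / 15 mg/kg reference price.
#'
#' @param weight Patient weight in kg, `> 0`.
#' @param dose Dose in mg/kg, `>= 0`.
#' @param ref_cost Reference cost per cycle at 70 kg and 15 mg/kg.
#' @return Cost in USD per 3-week cycle.
#' @examples
#' bev_cost(70, 15)   # 117.60
#' bev_cost(140, 15)  # 235.20
#' @export
bev_cost <- function(weight, dose = 15, ref_cost = 117.60) {
  check_number(weight, "weight", lower = .Machine$double.xmin)
  check_number(dose, "dose", lower = 0)
  check_number(ref_cost, "ref_cost", lower = 0)
  ref_cost * (weight / 70) * (dose / 15)
}

#' Treatment strategy specification
#'
#' One arm of the comparison: survival models, drug components with their
#' per-cycle prices and time-on-treatment curves, supportive-care and
#' post-progression costs, adverse-event profile, and utilities. Time on
#' treatment is modelled per drug component as an exponential curve with the
#' trial's median duration, multiplied by the alive fraction; drug and
#' administration costs accrue on that occupancy.
#'
#' @param name Strategy label.
#' @param os_model,pfs_model [parametric_survival()] laws (post hazard-ratio).
#' @param drug_components Tibble with columns `component`, `cost_per_cycle`
#'   (USD per 3-week cycle) and `duration_median` (months); administration
#'   costs follow the longest-duration component.
#' @param admin_cost USD per administration cycle.
#' @param imaging_cost_6wk Imaging cost per 6 weeks (half is charged per
#'   3-week cycle).
#' @param other_care_weekly Supportive-care cost per week, all alive states.
#' @param post_progression_cost USD per cycle in the progressed state.
#' @param eol_cost One-off end-of-life cost at the transition to death.
#' @param ae_profile Tibble with columns `ae`, `incidence`, `cost`,
#'   `disutility` (grade 3-4 events; applied once at model entry).
#' @param discontinuation_rate Trial rate of discontinuation due to adverse
#'   events (retained trial statistic; the cost engine uses the observed
#'   time-on-treatment medians instead).
#' @param utility_pf,utility_pd Health-state utilities in `[0, 1]`.
#' @param duration_cap Months after which drug and administration costs stop
#'   (`Inf` = treat per the duration curves).
#' @param societal Either `NULL` (payer perspective) or a list with
#'   `caregiver_cycle`, `patient_time`, `travel` (USD; caregiver accrues per
#'   cycle alive, the other two per administration visit).
#' @param price_multiplier Multiplier on all drug component prices (used by
#'   the price-reduction threshold search).
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name, os_model, pfs_model, drug_components,
                          admin_cost, imaging_cost_6wk, other_care_weekly,
                          post_progression_cost, eol_cost, ae_profile,
                          discontinuation_rate = NA_real_,
                          utility_pf = 0.78, utility_pd = 0.68,
                          duration_cap = Inf, societal = NULL,
                          price_multiplier = 1) {
  stopifnot(inherits(os_model, "parametric_survival"),
            inherits(pfs_model, "parametric_survival"))
  drug_components <- as_tibble(drug_components)
  stopifnot(all(c("component", "cost_per_cycle", "duration_median") %in%
                  names(drug_components)))
  for (nm in c(admin_cost, imaging_cost_6wk, other_care_weekly,
               post_progression_cost, eol_cost, drug_components$cost_per_cycle)) {
    check_number(nm, "cost", lower = 0)
  }
  check_number(utility_pf, "utility_pf", lower = 0, upper = 1)
  check_number(utility_pd, "utility_pd", lower = 0, upper = 1)
  check_number(duration_cap, "duration_cap", lower = 1e-9, finite = FALSE)
  check_number(price_multiplier, "price_multiplier", lower = 0)
  ae_profile <- as_tibble(ae_profile)
  stopifnot(all(c("ae", "incidence", "cost", "disutility") %in%
                  names(ae_profile)),
            all(ae_profile$incidence >= 0 & ae_profile$incidence <= 1))
  structure(list(name = name, os_model = os_model, pfs_model = pfs_model,
                 drug_components = drug_components, admin_cost = admin_cost,
                 imaging_cost_6wk = imaging_cost_6wk,
                 other_care_weekly = other_care_weekly,
                 post_progression_cost = post_progression_cost,
                 eol_cost = eol_cost, ae_profile = ae_profile,
                 discontinuation_rate = discontinuation_rate,
                 utility_pf = utility_pf, utility_pd = utility_pd,
                 duration_cap = duration_cap, societal = societal,
                 price_multiplier = price_multiplier),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy_spec> %s | drug %s/cycle | u(PF)=%.2f u(PD)=%.2f\n",
              x$name,
              paste(sprintf("%s %.2f", x$drug_components$component,
                            x$drug_components$cost_per_cycle), collapse = " + "),
              x$utility_pf, x$utility_pd))
  invisible(x)
}

#' Adverse-event burden of a strategy
#'
#' One-off cost and QALY decrement applied at model entry:
#' `sum(incidence * cost)` and `sum(incidence * disutility)`.
#'
#' @param strategy A [strategy_spec()].
#' @return A tibble with columns `ae_cost` and `ae_disutility`.
#' @examples
#' ae_burden(sorafenib_strategy())  # cost ~24.4 USD, decrement ~0.0149
#' @export
ae_burden <- function(strategy) {
  stopifnot(inherits(strategy, "strategy_spec"))
  pr <- strategy$ae_profile
  tibble(ae_cost = sum(pr$incidence * pr$cost),
         ae_disutility = sum(pr$incidence * pr$disutility))
}

#' Default strategies from the parameter table
#'
#' Build the two comparator arms from [default_parameters()] (optionally with
#' overridden values). The sorafenib survival models are the Weibull laws of
#' the parameter table; the atezolizumab-bevacizumab arm applies the OS and
#' PFS hazard ratios to them.
#'
#' @param values Named list of parameter values; defaults to the base case.
#' @return A `strategy_spec`.
#' @examples
#' atezo_bev_strategy()
#' sorafenib_strategy()
#' @name default_strategies
#' @export
atezo_bev_strategy <- function(values = base_values()) {
  v <- values
  os <- apply_hazard_ratio(
    parametric_survival("weibull", rate = v$weibull_os_rate,
                        shape = v$weibull_os_shape), v$hr_os)
  pfs <- apply_hazard_ratio(
    parametric_survival("weibull", rate = v$weibull_pfs_rate,
                        shape = v$weibull_pfs_shape), v$hr_pfs)
  strategy_spec(
    name = "atezolizumab-bevacizumab",
    os_model = os, pfs_model = pfs,
    drug_components = tibble(
      component = c("atezolizumab", "bevacizumab"),
      cost_per_cycle = c(v$cost_atezo,
                         bev_cost(v$weight_kg, v$bev_dose_mg_kg,
                                  v$cost_bev_ref)),
      duration_median = c(v$duration_atezo_median, v$duration_bev_median)),
    admin_cost = v$cost_admin, imaging_cost_6wk = v$cost_imaging_6wk,
    other_care_weekly = v$cost_other_weekly,
    post_progression_cost = v$cost_pp_ab, eol_cost = v$cost_eol,
    ae_profile = tibble(
      ae = c("diarrhea", "hand-foot syndrome", "hypertension", "bilirubin"),
      incidence = c(v$ae_ab_diarrhea, v$ae_ab_hfs, v$ae_ab_hypertension,
                    v$ae_ab_bilirubin),
      cost = c(v$cost_ae_diarrhea, v$cost_ae_hfs, v$cost_ae_hypertension,
               v$cost_ae_bilirubin),
      disutility = c(v$disutil_diarrhea, v$disutil_hfs,
                     v$disutil_hypertension, v$disutil_bilirubin)),
    discontinuation_rate = v$discontinuation_ab,
    utility_pf = v$util_pf_ab, utility_pd = v$util_pd,
    societal = societal_costs(v))
}

#' @rdname default_strategies
#' @export
sorafenib_strategy <- function(values = base_values()) {
  v <- values
  os <- parametric_survival("weibull", rate = v$weibull_os_rate,
                            shape = v$weibull_os_shape)
  pfs <- parametric_survival("weibull", rate = v$weibull_pfs_rate,
                             shape = v$weibull_pfs_shape)
  strategy_spec(
    name = "sorafenib",
    os_model = os, pfs_model = pfs,
    drug_components = tibble(component = "sorafenib",
                             cost_per_cycle = v$cost_sorafenib,
                             duration_median = v$duration_sor_median),
    admin_cost = v$cost_admin, imaging_cost_6wk = v$cost_imaging_6wk,
    other_care_weekly = v$cost_other_weekly,
    post_progression_cost = v$cost_pp_sor, eol_cost = v$cost_eol,
    ae_profile = tibble(
      ae = c("diarrhea", "hand-foot syndrome", "hypertension", "bilirubin"),
      incidence = c(v$ae_sor_diarrhea, v$ae_sor_hfs, v$ae_sor_hypertension,
                    v$ae_sor_bilirubin),
      cost = c(v$cost_ae_diarrhea, v$cost_ae_hfs, v$cost_ae_hypertension,
               v$cost_ae_bilirubin),
      disutility = c(v$disutil_diarrhea, v$disutil_hfs,
                     v$disutil_hypertension, v$disutil_bilirubin)),
    discontinuation_rate = v$discontinuation_sor,
    utility_pf = v$util_pf_sor, utility_pd = v$util_pd,
    societal = societal_costs(v))
}

societal_costs <- function(v) {
  list(caregiver_cycle = v$cost_caregiver_cycle,
       patient_time = v$cost_patient_time,
       travel = v$cost_travel,
       active = FALSE)
}

#' Cap the paid duration of therapy
#'
#' Drug and administration costs cease after `cap` months; the effectiveness
#' curves are unchanged (a cost-only transform).
#'
#' @param strategy A [strategy_spec()].
#' @param cap Months, `> 0`.
#' @return The modified strategy.
#' @export
apply_duration_cap <- function(strategy, cap) {
  stopifnot(inherits(strategy, "strategy_spec"))
  check_number(cap, "cap", lower = 1e-9, finite = FALSE)
  strategy$duration_cap <- cap
  strategy
}

#' Switch a strategy to the societal perspective
#'
#' Adds caregiver cost per cycle in alive states and patient-time plus travel
#' costs per administration visit.
#'
#' @param strategy A [strategy_spec()].
#' @return The modified strategy.
#' @export
societal_view <- function(strategy) {
  stopifnot(inherits(strategy, "strategy_spec"))
  if (is.null(strategy$societal)) {
    strategy$societal <- list(caregiver_cycle = 0, patient_time = 0,
                              travel = 0, active = TRUE)
  }
  strategy$societal$active <- TRUE
  strategy
}

#' Scale the prices of a strategy's drug components
#'
#' @param strategy A [strategy_spec()].
#' @param multiplier Price multiplier in `[0, 1]` for a reduction.
#' @return The modified strategy.
#' @export
scale_drug_price <- function(strategy, multiplier) {
  stopifnot(inherits(strategy, "strategy_spec"))
  check_number(multiplier, "multiplier", lower = 0)
  strategy$price_multiplier <- strategy$price_multiplier * multiplier
  strategy
}
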