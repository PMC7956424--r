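ab_os <- function() apply_hazard_ratio(sor_os_law(), 0.58)

# survival curve implied by the per-cycle transition structure
survival_from_transitions <- function(trans) {
  cumprod(1 - trans$p_death)
}

test_that("extrapolate mode reproduces the unmodified model", {
  st <- model_settings()
  lt <- make_life_table()
  plain <- run_strategy(atezo_bev_strategy(), st, lt)
  extrap <- run_strategy(atezo_bev_strategy(), st, lt,
                         scenario_spec("extrapolate"))
  expect_equal(glance(extrap), glance(plain), tolerance = 1e-12)
})

test_that("optimistic cure freezes survival when background mortality is zero", {
  st <- model_settings()
  trans <- build_transitions(atezo_bev_strategy(), st, zero_life_table(),
                             scenario_spec("optimistic"))
  s <- survival_from_transitions(trans)
  post <- trans$t0 >= 17
  expect_true(all(abs(diff(s[post]) ) < 1e-15))
  expect_true(all(trans$p_death[post] == 0))
})

test_that("pessimistic calibration reproduces its anchor", {
  lt <- make_life_table()
  sc <- scenario_spec("pessimistic", anchor = 0.15, anchor_time = 36)
  h <- longterm_hazard(ab_os(), sc, lt, start_age = 65)
  expect_gt(calibrate_excess_hazard(ab_os(), sc, lt, 65), 0)
  # integrate the piecewise hazard to 36 months
  grid <- seq(0, 36, by = 0.01)
  hz <- h(grid + 0.005)
  s36 <- exp(-sum(hz * 0.01))
  # compare against the hazard-only disease component + background:
  # the calibration targets the all-cause curve
  expect_equal(s36, 0.15, tolerance = 1e-3)
})

test_that("the calibrated all-cause curve is continuous at the switch", {
  lt <- make_life_table()
  for (mode in c("extrapolate", "optimistic")) {
    h <- longterm_hazard(ab_os(), scenario_spec(mode), lt, 65)
    grid <- seq(0, 30, by = 0.001)
    s <- exp(-cumsum(h(grid + 0.0005) * 0.001))
    k <- which.min(abs(grid - 17))
    expect_lt(abs(s[k + 1] - s[k]), 1e-3)  # no jump, just hazard change
  }
})

test_that("an unattainable anchor errors; one above the tail warns", {
  lt <- make_life_table()
  too_high <- scenario_spec("pessimistic", anchor = 0.6, anchor_time = 36)
  expect_error(calibrate_excess_hazard(ab_os(), too_high, lt, 65),
               class = "hccea_calibration_error")
  # an anchor just under the 17-month survival exceeds what any
  # non-negative excess hazard can produce once background mortality accrues
  above_tail <- scenario_spec("pessimistic", anchor = 0.53, anchor_time = 36)
  expect_warning(calibrate_excess_hazard(ab_os(), above_tail, lt, 65),
                 "negative")
})

test_that("survival at 36 months orders pessimistic <= extrapolate <= optimistic", {
  st <- model_settings()
  lt <- make_life_table()
  strat <- atezo_bev_strategy()
  s36 <- function(scenario) {
    trans <- build_transitions(strat, st, lt, scenario)
    s <- survival_from_transitions(trans)
    s[which.min(abs(trans$t1 - 36))]
  }
  s_pess <- s36(scenario_spec("pessimistic", anchor = 0.15))
  s_base <- s36(NULL)
  s_opt <- s36(scenario_spec("optimistic"))
  expect_lte(s_pess, s_base)
  expect_lte(s_base, s_opt)
})

test_that("QALYs order optimistic >= base >= pessimistic (attainable anchor)", {
  st <- model_settings()
  lt <- make_life_table()
  q <- function(scenario) {
    evaluate_model(scenario = scenario, settings = st,
                   life_table = lt)$ab$outcome$qalys
  }
  expect_gte(q(scenario_spec("optimistic")), q(NULL))
  expect_gte(q(NULL), q(scenario_spec("pessimistic", anchor = 0.15)))
})

test_that("duration caps are cost-only transforms", {
  st <- model_settings()
  lt <- make_life_table()
  base <- run_strategy(atezo_bev_strategy(), st, lt)
  capped_far <- run_strategy(apply_duration_cap(atezo_bev_strategy(), 120),
                             st, lt)
  expect_equal(glance(capped_far), glance(base), tolerance = 1e-12)
  cap24 <- glance(run_strategy(apply_duration_cap(atezo_bev_strategy(), 24),
                               st, lt))
  cap12 <- glance(run_strategy(apply_duration_cap(atezo_bev_strategy(), 12),
                               st, lt))
  expect_lt(cap12$total_cost, cap24$total_cost)
  expect_equal(cap12$qalys, cap24$qalys, tolerance = 1e-12)
  expect_equal(cap12$life_years, glance(base)$life_years, tolerance = 1e-12)
})

test_that("the societal perspective adds cost and only cost", {
  st <- model_settings()
  lt <- make_life_table()
  payer <- evaluate_model(settings = st, life_table = lt)
  soc <- evaluate_model(settings = st, life_table = lt, societal = TRUE)
  expect_equal(soc$comparison$delta_qalys, payer$comparison$delta_qalys,
               tolerance = 1e-12)
  expect_gt(soc$comparison$icer_qaly, payer$comparison$icer_qaly)
  # zeroed societal inputs change nothing
  v <- base_values()
  v$cost_caregiver_cycle <- 0
  v$cost_patient_time <- 0
  v$cost_travel <- 0
  zeroed <- evaluate_model(v, st, lt, societal = TRUE)
  expect_equal(zeroed$comparison$icer_qaly, payer$comparison$icer_qaly,
               tolerance = 1e-12)
})
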