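test_that("transition matrices conserve probability and absorb death", {
  st <- model_settings()
  lt <- make_life_table()
  for (strat in list(atezo_bev_strategy(), sorafenib_strategy())) {
    arr <- as_transition_array(build_transitions(strat, st, lt))
    sums <- apply(arr, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(arr[, "dead", "dead"] == 1))
    expect_true(all(arr >= 0))
  }
})

test_that("occupancy stays a probability vector and death is monotone", {
  st <- model_settings()
  lt <- make_life_table()
  res <- run_strategy(sorafenib_strategy(), st, lt)
  tr <- tidy(res)
  expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-12))
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(tr$pf >= 0 & tr$pd >= 0))
})

test_that("negligible hazards keep the cohort progression-free", {
  quiet <- strategy_spec(
    name = "quiet",
    os_model = parametric_survival("exponential", rate = 1e-12),
    pfs_model = parametric_survival("exponential", rate = 1e-12),
    drug_components = tibble::tibble(component = "none", cost_per_cycle = 0,
                                     duration_median = 6),
    admin_cost = 0, imaging_cost_6wk = 0, other_care_weekly = 0,
    post_progression_cost = 0, eol_cost = 0,
    ae_profile = tibble::tibble(ae = "none", incidence = 0, cost = 0,
                                disutility = 0),
    utility_pf = 1, utility_pd = 1)
  st <- model_settings(discount_rate = 0)
  res <- run_strategy(quiet, st, zero_life_table())
  tr <- tidy(res)
  expect_true(all(tr$pf > 1 - 1e-9))
  # immortal cohort with utility 1 and no discounting: LY = QALY = horizon
  out <- glance(res)
  expect_equal(out$life_years, 86 * 21 / 365.25, tolerance = 1e-9)
  expect_equal(out$qalys, out$life_years, tolerance = 1e-12)
  expect_equal(out$total_cost, 0)
})

test_that("first-cycle death probability matches the closed-form hazard sum", {
  st <- model_settings()
  lt <- make_life_table()
  tr <- build_transitions(sorafenib_strategy(), st, lt)
  delta <- st$cycle_months
  h_hcc <- -log(survival_at(sor_os_law(), delta)) / delta
  h_bg <- -log(1 - lt$qx[lt$age == 65]) / 12
  expect_equal(tr$p_death[1], 1 - exp(-(h_hcc + h_bg) * delta),
               tolerance = 1e-12)
})

test_that("discounting lowers accruals and half-cycle correction is small", {
  lt <- make_life_table()
  res <- run_strategy(atezo_bev_strategy(), model_settings(), lt)
  out <- glance(res)
  expect_lt(out$qalys, out$qalys_undisc)
  expect_lt(out$total_cost, out$total_cost_undisc)
  expect_lte(out$qalys, out$life_years)  # utilities <= 1
  no_hcc <- run_strategy(atezo_bev_strategy(),
                         model_settings(half_cycle_correction = FALSE), lt)
  cycle_years <- 21 / 365.25
  expect_lt(abs(glance(no_hcc)$life_years - out$life_years), cycle_years)
})

test_that("adverse-event burden matches the hand arithmetic", {
  ab <- ae_burden(sorafenib_strategy())
  expect_equal(ab$ae_cost,
               0.051 * 88.38 + 0.083 * 145.65 + 0.122 * 64.01 + 0.064 * 0,
               tolerance = 1e-12)
  expect_equal(ab$ae_disutility, 0.051 * 0.103 + 0.083 * 0.116,
               tolerance = 1e-12)
  ab2 <- ae_burden(atezo_bev_strategy())
  expect_equal(ab2$ae_disutility, 0.018 * 0.103, tolerance = 1e-12)
  none <- sorafenib_strategy()
  none$ae_profile$incidence <- 0
  expect_equal(unlist(ae_burden(none)), c(ae_cost = 0, ae_disutility = 0))
})

test_that("bevacizumab cost scales linearly in weight and dose", {
  expect_equal(bev_cost(70, 15), 117.60)
  expect_equal(bev_cost(140, 15), 235.20)
  expect_equal(bev_cost(70, 0), 0)
  expect_equal(bev_cost(100, 10), 117.60 * (100 / 70) * (10 / 15))
  expect_error(bev_cost(-1, 15), class = "hccea_domain_error")
})

test_that("lower hazard ratios extend life; higher prices raise cost", {
  lt <- make_life_table()
  st <- model_settings()
  base <- base_values()
  ly_at <- function(hr) {
    v <- base; v$hr_os <- hr
    glance(run_strategy(atezo_bev_strategy(v), st, lt))$life_years
  }
  lys <- vapply(c(0.42, 0.58, 0.79, 1), ly_at, numeric(1))
  expect_true(all(diff(lys) < 0))
  cost_at <- function(price) {
    v <- base; v$cost_atezo <- price
    glance(run_strategy(atezo_bev_strategy(v), st, lt))$total_cost
  }
  costs <- vapply(c(7535.33, 9419.16, 11302.99), cost_at, numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("longer horizons accrue weakly more life-years and cost", {
  lt <- make_life_table()
  base <- base_values()
  res <- purrr::map(c(5, 10, 40), function(h) {
    st <- model_settings(horizon_years = h)
    glance(run_strategy(atezo_bev_strategy(base), st, lt))
  })
  ly <- purrr::map_dbl(res, "life_years")
  cost <- purrr::map_dbl(res, "total_cost")
  expect_true(all(diff(ly) >= 0))
  expect_true(all(diff(cost) >= 0))
})

test_that("cohort recursion matches a 200,000-subject microsimulation", {
  st <- model_settings()
  lt <- make_life_table()
  strat <- atezo_bev_strategy()
  trans <- build_transitions(strat, st, lt)
  cohort <- run_cohort(strat, st, trans)
  micro <- microsim_oracle(strat, st, trans, n_subjects = 200000, seed = 99)
  out <- glance(cohort)
  expect_equal(micro$life_years, out$life_years, tolerance = 0.005)
  expect_equal(micro$qalys, out$qalys, tolerance = 0.005)
})
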