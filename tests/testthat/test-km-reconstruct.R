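test_that("a fully observed cohort reconstructs exactly", {
  set.seed(21)
  times <- sort(round(runif(20, 1, 24), 1))
  co <- tibble::tibble(time = times, event = 1L)
  grid <- c(0, sort(unique(times)))
  cv <- make_km_curve(co, grid, risk_table_times = c(0, 6, 12, 18, 24))
  ipd <- reconstruct_ipd(cv)
  expect_equal(nrow(ipd), 20)
  got <- dplyr::count(dplyr::filter(ipd, event == 1), time)
  want <- dplyr::count(co, time)
  expect_equal(got, want)
})

test_that("round trip through a censored Weibull cohort stays within 0.02 sup-norm", {
  co <- simulate_survival(sor_os_law(), 500, censor_rate = 0.02,
                          max_follow_up = 40, seed = 31)
  expect_gt(mean(co$event == 0), 0.1)  # materially censored
  grid <- seq(0, 40, by = 0.25)
  cv <- make_km_curve(co, grid, risk_table_times = seq(0, 40, by = 4))
  ipd <- reconstruct_ipd(cv)
  expect_equal(nrow(ipd), 500)
  km_in <- km_estimate(co, grid)$survival
  km_out <- km_estimate(ipd, grid)$survival
  expect_lt(max(abs(km_in - km_out)), 0.02)
})

test_that("round trip holds across generating laws and censoring levels", {
  laws <- list(sor_os_law(), sor_pfs_law(),
               apply_hazard_ratio(sor_os_law(), 0.58))
  for (i in seq_along(laws)) {
    co <- simulate_survival(laws[[i]], 300, censor_rate = 0.015 * i,
                            max_follow_up = 36, seed = 40 + i)
    grid <- seq(0, 36, by = 0.5)
    cv <- make_km_curve(co, grid, risk_table_times = seq(0, 36, by = 6))
    ipd <- reconstruct_ipd(cv)
    expect_equal(nrow(ipd), 300)
    expect_lt(max(abs(km_estimate(co, grid)$survival -
                        km_estimate(ipd, grid)$survival)), 0.02)
  }
})

test_that("a flat curve yields no events before the final time", {
  cv <- km_curve(coords = tibble::tibble(time = c(0, 5, 10, 15),
                                         survival = 1),
                 risk_table = tibble::tibble(time = c(0, 15),
                                             n_risk = c(50L, 50L)))
  ipd <- reconstruct_ipd(cv)
  expect_equal(sum(ipd$event), 0)
  expect_true(all(ipd$time == 15))
})

test_that("a known total event count rescales the allocation", {
  co <- simulate_survival(sor_os_law(), 200, censor_rate = 0.02,
                          max_follow_up = 30, seed = 55)
  cv <- make_km_curve(co, seq(0, 30, by = 0.5), seq(0, 30, by = 6))
  ipd <- reconstruct_ipd(cv, total_events = sum(co$event))
  expect_equal(sum(ipd$event), sum(co$event))
})

test_that("inconsistent curves are rejected with the offending location", {
  expect_error(
    km_curve(coords = tibble::tibble(time = c(0, 2, 4),
                                     survival = c(1, 0.5, 0.8)),
             risk_table = tibble::tibble(time = c(0, 4), n_risk = c(10L, 5L))),
    "rises", class = "hccea_validation_error")
  expect_error(
    km_curve(coords = tibble::tibble(time = c(0, 2, 4),
                                     survival = c(1, 0.8, 0.6)),
             risk_table = tibble::tibble(time = c(0, 4), n_risk = c(10L, 12L))),
    "increase", class = "hccea_validation_error")
  # small digitization wobble is repaired, with a message
  expect_message(
    km_curve(coords = tibble::tibble(time = c(0, 2, 4),
                                     survival = c(1, 0.800, 0.801)),
             risk_table = tibble::tibble(time = c(0, 4), n_risk = c(10L, 8L))),
    "repaired")
})

test_that("our product-limit estimator matches survival::survfit on random cohorts", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    time <- round(rexp(n, 0.1) + 0.05, 2)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1L
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    grid <- sort(unique(c(0, time, time / 2)))
    ours <- km_estimate(tibble::tibble(time = time, event = event),
                        grid)$survival
    theirs <- summary(fit, times = grid, extend = TRUE)$surv
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})
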