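test_that("the exponential fit equals the closed-form MLE", {
  co <- simulate_survival(parametric_survival("exponential", rate = 0.07),
                          800, censor_rate = 0.03, max_follow_up = 40,
                          seed = 14)
  fit <- fit_parametric(co, "exponential")
  expect_equal(fit$model$params$rate, sum(co$event) / sum(co$time),
               tolerance = 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$log_likelihood)
})

test_that("Weibull fitting recovers the generating parameters", {
  co <- simulate_survival(sor_os_law(), 5000, censor_rate = 0.016,
                          max_follow_up = 45, seed = 15)
  expect_gt(mean(co$event == 0), 0.12)
  fit <- fit_parametric(co, "weibull")
  expect_true(fit$converged)
  expect_equal(fit$model$params$rate, 0.027, tolerance = 0.05)
  expect_equal(fit$model$params$shape, 1.286, tolerance = 0.05)
  # optimum at least as good as the truth
  truth_ll <- sum(ifelse(co$event == 1,
                         log(hazard_at(sor_os_law(), co$time)) +
                           log(survival_at(sor_os_law(), co$time)),
                         log(survival_at(sor_os_law(), co$time))))
  expect_gte(fit$log_likelihood, truth_ll - 1e-6)
})

test_that("Weibull fit agrees with flexsurv as an independent oracle", {
  co <- simulate_survival(sor_os_law(), 1500, censor_rate = 0.02,
                          max_follow_up = 40, seed = 16)
  ours <- fit_parametric(co, "weibull")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                               data = co, dist = "weibull")
  shape_ref <- unname(ref$res["shape", "est"])
  rate_ref <- unname(ref$res["scale", "est"])^(-shape_ref)
  expect_equal(ours$model$params$shape, shape_ref, tolerance = 1e-4)
  expect_equal(ours$model$params$rate, rate_ref, tolerance = 1e-4)
  expect_equal(ours$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
})

test_that("model selection prefers the generating family and is order-invariant", {
  co <- simulate_survival(sor_pfs_law(), 4000, censor_rate = 0.02,
                          max_follow_up = 30, seed = 17)
  sel <- select_model(co)
  expect_equal(nrow(sel), 4)
  expect_true(all(diff(sel$aic) >= 0))
  expect_lt(which(sel$family == "weibull"),
            which(sel$family == "exponential"))
  # exponential data: the one-parameter model sits within 2 AIC of Weibull
  co_exp <- simulate_survival(parametric_survival("exponential", rate = 0.08),
                              4000, censor_rate = 0.02, max_follow_up = 40,
                              seed = 18)
  sel_exp <- select_model(co_exp)
  a <- sel_exp$aic[sel_exp$family == "exponential"]
  b <- sel_exp$aic[sel_exp$family == "weibull"]
  expect_lt(abs(a - b), 2 + 1e-9)
  # permuting subjects leaves the ranking unchanged
  set.seed(19)
  sel_perm <- select_model(co[sample(nrow(co)), ])
  expect_equal(sel_perm$family, sel$family)
  expect_equal(sel_perm$aic, sel$aic, tolerance = 1e-9)
})

test_that("degenerate inputs raise fitting errors", {
  all_cens <- tibble::tibble(time = c(1, 2, 3), event = 0L)
  expect_error(fit_parametric(all_cens, "weibull"),
               class = "hccea_fitting_error")
  one_event <- tibble::tibble(time = c(1, 2, 3), event = c(1L, 0L, 0L))
  expect_error(fit_parametric(one_event, "weibull"),
               class = "hccea_fitting_error")
})

test_that("tidy and glance expose the fit in broom style", {
  co <- simulate_survival(sor_os_law(), 300, seed = 20)
  fit <- fit_parametric(co, "weibull")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("rate", "shape"))
  gl <- glance(fit)
  expect_named(gl, c("family", "log_likelihood", "aic", "n", "n_events",
                     "converged"))
  expect_equal(gl$n, 300)
})
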