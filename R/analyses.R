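#' Deterministic model evaluation at given parameter values
#'
#' Builds both strategies from a named list of parameter values, runs the
#' cohort model under an optional long-term scenario, and returns the
#' incremental comparison of atezolizumab-bevacizumab vs sorafenib.
#'
#' @param values Named list of parameter values (see [default_parameters()]);
#'   defaults to the base case.
#' @param settings A [model_settings()].
#' @param life_table Life table tibble.
#' @param scenario Optional [scenario_spec()].
#' @param cap_ab Duration cap (months) on the atezolizumab-bevacizumab arm.
#' @param societal Use the societal perspective for both arms.
#' @param price_mult Price multiplier on the atezolizumab-bevacizumab drug
#'   components.
#' @return A list with `ab` and `sor` (`cohort_result`s) and `comparison`
#'   (the [compare()] row).
#' @export
evaluate_model <- function(values = base_values(),
                           settings = model_settings(),
                           life_table = make_life_table(),
                           scenario = NULL, cap_ab = Inf, societal = FALSE,
                           price_mult = 1) {
  ab <- atezo_bev_strategy(values)
  sor <- sorafenib_strategy(values)
  if (is.finite(cap_ab)) ab <- apply_duration_cap(ab, cap_ab)
  if (societal) {
    ab <- societal_view(ab)
    sor <- societal_view(sor)
  }
  if (price_mult != 1) ab <- scale_drug_price(ab, price_mult)
  res_ab <- run_strategy(ab, settings, life_table, scenario)
  res_sor <- run_strategy(sor, settings, life_table, scenario)
  list(ab = res_ab, sor = res_sor,
       comparison = compare(res_ab, res_sor, settings$wtp_thresholds))
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the model at the low and high end of each parameter's range,
#' holding everything else at base, and ranks parameters by the absolute
#' ICER spread (tornado ordering).
#'
#' @param params Parameter table from [default_parameters()].
#' @inheritParams evaluate_model
#' @return A `tornado` tibble: `parameter`, `lo`, `hi`, `icer_lo`,
#'   `icer_hi`, `icer_base`, `spread`, sorted by descending spread. Rows
#'   where the model fails at an endpoint carry `NA` and a `failed` flag.
#' @export
one_way_dsa <- function(params = default_parameters(),
                        settings = model_settings(),
                        life_table = make_life_table(), scenario = NULL) {
  base <- utils::modifyList(base_values(),
                            setNames(as.list(params$base), params$parameter))
  icer_base <- evaluate_model(base, settings, life_table,
                              scenario)$comparison$icer_qaly
  varied <- params %>% filter(.data$dist != "fixed")
  rows <- purrr::pmap(
    list(varied$parameter, varied$base, varied$lo, varied$hi),
    function(pname, bval, lo, hi) {
      if (!(lo <= bval && bval <= hi)) {
        stop_hccea(sprintf("range for %s does not bracket its base value",
                           pname), class = "hccea_config_error")
      }
      icers <- purrr::map_dbl(c(lo, hi), function(v) {
        vals <- base
        vals[[pname]] <- v
        tryCatch(
          evaluate_model(vals, settings, life_table, scenario)$comparison$icer_qaly,
          error = function(e) NA_real_)
      })
      tibble(parameter = pname, lo = lo, hi = hi,
             icer_lo = icers[1], icer_hi = icers[2],
             failed = anyNA(icers))
    })
  out <- purrr::list_rbind(rows) %>%
    mutate(icer_base = icer_base,
           spread = abs(.data$icer_hi - .data$icer_lo)) %>%
    arrange(desc(.data$spread))
  class(out) <- c("hccea_tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of the Table-of-parameters uncertainty through
#' both arms on common draws, using the vectorized cohort engine. The
#' Weibull survival parameters themselves are held fixed (no distribution is
#' stated for them); everything else follows its stated distribution.
#'
#' @param n_iter Number of iterations, `>= 1`.
#' @param params Parameter table.
#' @inheritParams evaluate_model
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @return A `psa_result`: list with `draws` (per-iteration tibble with both
#'   arms' cost and QALYs and the incremental values), `n_iter`, `seed`,
#'   `wtps`, and `acceptability` (fraction of iterations with positive
#'   incremental net monetary benefit per threshold).
#' @export
psa <- function(n_iter = 1e4, params = default_parameters(),
                settings = model_settings(), life_table = make_life_table(),
                scenario = NULL, cap_ab = Inf, societal = FALSE,
                price_mult = 1, seed = 1L) {
  check_number(n_iter, "n_iter", lower = 1)
  draws <- sample_parameter_draws(n_iter, params, seed)
  arms <- evaluate_arms_vec(draws, settings, life_table, scenario,
                            cap_ab = cap_ab, societal = societal,
                            price_mult = price_mult)
  d <- tibble(iteration = seq_len(n_iter),
              cost_ab = arms$ab$cost, qaly_ab = arms$ab$qaly,
              cost_sor = arms$sor$cost, qaly_sor = arms$sor$qaly) %>%
    mutate(delta_cost = .data$cost_ab - .data$cost_sor,
           delta_qalys = .data$qaly_ab - .data$qaly_sor)
  wtps <- settings$wtp_thresholds
  acc <- vapply(wtps, function(w) mean(w * d$delta_qalys - d$delta_cost > 0),
                numeric(1))
  structure(list(draws = d, n_iter = as.integer(n_iter), seed = as.integer(seed),
                 wtps = wtps,
                 acceptability = tibble(wtp = wtps, probability = acc)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n_iter, x$seed))
  print(x$acceptability)
  invisible(x)
}

#' @rdname psa
#' @param x A `psa_result`.
#' @param ... Unused.
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @rdname psa
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  ci <- stats::quantile(x$draws$delta_cost / x$draws$delta_qalys,
                        c(0.025, 0.975), na.rm = TRUE)
  out <- tibble(n_iter = x$n_iter,
                mean_delta_cost = mean(x$draws$delta_cost),
                mean_delta_qalys = mean(x$draws$delta_qalys),
                icer_of_means = mean(x$draws$delta_cost) /
                  mean(x$draws$delta_qalys),
                icer_q2.5 = ci[[1]], icer_q97.5 = ci[[2]])
  for (i in seq_along(x$wtps)) {
    out[[paste0("acceptability_", format(x$wtps[i], scientific = FALSE))]] <-
      x$acceptability$probability[i]
  }
  out
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa_result A [psa()] result.
#' @param wtps Grid of willingness-to-pay thresholds (USD/QALY).
#' @return A tibble `wtp`, `probability` (fraction of iterations with
#'   positive incremental net monetary benefit).
#' @export
ceac <- function(psa_result, wtps = seq(0, 3e5, by = 5e3)) {
  stopifnot(inherits(psa_result, "psa_result"))
  d <- psa_result$draws
  tibble(wtp = wtps,
         probability = vapply(wtps, function(w)
           mean(w * d$delta_qalys - d$delta_cost > 0), numeric(1)))
}

#' Price-reduction threshold search
#'
#' Smallest fractional price reduction of the atezolizumab-bevacizumab drug
#' components (both scaled together) at which the ICER vs sorafenib meets a
#' willingness-to-pay threshold, found by bisection to 0.1% resolution.
#'
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @inheritParams evaluate_model
#' @param resolution Bisection resolution on the reduction fraction.
#' @return A one-row tibble: `wtp`, `reduction` (in `[0, 1]`, `NA` when no
#'   reduction in `[0, 1]` attains the threshold), `icer_at_reduction`.
#' @export
price_threshold <- function(wtp, values = base_values(),
                            settings = model_settings(),
                            life_table = make_life_table(),
                            scenario = NULL, resolution = 1e-3) {
  icer_at <- function(r) {
    evaluate_model(values, settings, life_table, scenario,
                   price_mult = 1 - r)$comparison
  }
  meets <- function(cmp) {
    cmp$label == "dominant" ||
      (cmp$label == "icer" && cmp$icer_qaly <= wtp)
  }
  c0 <- icer_at(0)
  if (meets(c0)) {
    return(tibble(wtp = wtp, reduction = 0, icer_at_reduction = c0$icer_qaly))
  }
  c1 <- icer_at(1)
  if (!meets(c1)) {
    return(tibble(wtp = wtp, reduction = NA_real_,
                  icer_at_reduction = c1$icer_qaly))
  }
  lo <- 0; hi <- 1
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (meets(icer_at(mid))) hi <- mid else lo <- mid
  }
  cmp <- icer_at(hi)
  tibble(wtp = wtp, reduction = hi, icer_at_reduction = cmp$icer_qaly)
}

#' Two-way deterministic sensitivity analysis
#'
#' Full-factorial ICER surface over two axes. Each axis is either a
#' parameter name from the parameter table, or one of the pseudo-parameters
#' `"price_reduction"` (fractional reduction of the atezolizumab-bevacizumab
#' price) and `"three_year_survival"` (post-switch hazard of the
#' atezolizumab-bevacizumab arm calibrated so 3-year survival equals the
#' axis value).
#'
#' @param param_x,param_y Axis names.
#' @param grid_x,grid_y Numeric grids.
#' @inheritParams evaluate_model
#' @return A tibble `x`, `y`, `icer` (one row per grid combination) with the
#'   axis names in attributes `"param_x"`/`"param_y"`.
#' @export
two_way_dsa <- function(param_x, grid_x, param_y, grid_y,
                        values = base_values(), settings = model_settings(),
                        life_table = make_life_table()) {
  stopifnot(is.numeric(grid_x), is.numeric(grid_y),
            all(is.finite(grid_x)), all(is.finite(grid_y)))
  eval_point <- function(px, vx, py, vy) {
    vals <- values
    price_mult <- 1
    scenario <- NULL
    for (pv in list(list(px, vx), list(py, vy))) {
      p <- pv[[1]]; v <- pv[[2]]
      if (p == "price_reduction") {
        price_mult <- price_mult * (1 - v)
      } else if (p == "three_year_survival") {
        scenario <- scenario_spec("pessimistic", anchor = v, anchor_time = 36)
      } else if (p %in% names(vals)) {
        vals[[p]] <- v
      } else {
        stop_hccea(sprintf("unknown axis '%s'", p),
                   class = "hccea_config_error")
      }
    }
    cmp <- tryCatch(
      suppressWarnings(
        evaluate_model(vals, settings, life_table, scenario,
                       price_mult = price_mult)$comparison),
      error = function(e) NULL)
    if (is.null(cmp)) NA_real_
    else if (cmp$label == "dominant") 0
    else cmp$icer_qaly
  }
  out <- tidyr::expand_grid(x = grid_x, y = grid_y) %>%
    mutate(icer = purrr::map2_dbl(.data$x, .data$y,
                                  ~eval_point(param_x, .x, param_y, .y)))
  attr(out, "param_x") <- param_x
  attr(out, "param_y") <- param_y
  out
}
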