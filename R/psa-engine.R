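# Vectorized evaluation of both arms across parameter draws.
#
# Mirrors run_cohort() cycle by cycle, with every quantity a vector across
# draws; for identical parameter values it reproduces the scalar engine to
# machine precision (asserted in the test suite). Survival laws are the
# Weibull forms of the default model (rate hr * lambda, shape gamma).

#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' Hazard ratios are drawn from normal distributions (sd from the stated 95%
#' CI) truncated just above zero; trial proportions from binomial
#' distributions with the trial arm sizes as denominators, divided back to
#' rates; costs, utilities and body weight from triangular distributions;
#' `fixed` rows stay at base value.
#'
#' @param n Number of draws.
#' @param params Parameter table from [default_parameters()].
#' @param seed Integer seed.
#' @return A tibble with `n` rows, one column per parameter.
#' @export
sample_parameter_draws <- function(n, params = default_parameters(),
                                   seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- purrr::pmap(params, function(parameter, base, lo, hi, dist, denom) {
    switch(dist,
      fixed = rep(base, n),
      normal = pmax(rnorm(n, base, (hi - lo) / (2 * qnorm(0.975))), 1e-6),
      binomial = rbinom(n, round(denom), base) / round(denom),
      triangular = rtriangular(n, lo, base, hi),
      stop_hccea(sprintf("unknown distribution '%s' for %s", dist, parameter),
                 class = "hccea_config_error"))
  })
  names(draws) <- params$parameter
  as_tibble(draws)
}

# draws: tibble (or 1-row list) of parameter values; returns list of two
# tibbles (ab, sor) with cost/qaly/ly per draw
evaluate_arms_vec <- function(draws, settings, life_table,
                              scenario = NULL, cap_ab = Inf,
                              societal = FALSE, price_mult = 1) {
  d <- draws
  n <- nrow(d)
  dm <- settings$cycle_months
  dy <- dm / 12
  sc <- settings$cycle_length_days / 21
  nc <- settings$n_cycles
  mode <- if (is.null(scenario)) "extrapolate" else scenario$mode
  sw <- if (is.null(scenario)) Inf else scenario$switch_time
  stops_ther <- !is.null(scenario) && isTRUE(scenario$cure_stops_therapy)
  stops_prog <- !is.null(scenario) && isTRUE(scenario$cure_stops_progression)

  lam_os_ab <- d$weibull_os_rate * d$hr_os
  lam_pfs_ab <- d$weibull_pfs_rate * d$hr_pfs
  gam_os <- d$weibull_os_shape
  gam_pfs <- d$weibull_pfs_shape

  h_ex <- if (mode == "pessimistic") {
    s_sw <- exp(-lam_os_ab * sw^gam_os)
    if (any(scenario$anchor >= s_sw)) {
      # keep the draw usable: hazard floor at 0 handled below
    }
    hbg_int <- integrate_bg_hazard(life_table, settings$start_age, 0,
                                   scenario$anchor_time)
    (log(s_sw / scenario$anchor) - hbg_int) / (scenario$anchor_time - sw)
  } else 0

  ae_cost_ab <- d$ae_ab_diarrhea * d$cost_ae_diarrhea +
    d$ae_ab_hfs * d$cost_ae_hfs +
    d$ae_ab_hypertension * d$cost_ae_hypertension +
    d$ae_ab_bilirubin * d$cost_ae_bilirubin
  ae_cost_sor <- d$ae_sor_diarrhea * d$cost_ae_diarrhea +
    d$ae_sor_hfs * d$cost_ae_hfs +
    d$ae_sor_hypertension * d$cost_ae_hypertension +
    d$ae_sor_bilirubin * d$cost_ae_bilirubin
  ae_dis_ab <- d$ae_ab_diarrhea * d$disutil_diarrhea +
    d$ae_ab_hfs * d$disutil_hfs +
    d$ae_ab_hypertension * d$disutil_hypertension +
    d$ae_ab_bilirubin * d$disutil_bilirubin
  ae_dis_sor <- d$ae_sor_diarrhea * d$disutil_diarrhea +
    d$ae_sor_hfs * d$disutil_hfs +
    d$ae_sor_hypertension * d$disutil_hypertension +
    d$ae_sor_bilirubin * d$disutil_bilirubin

  one_arm <- function(lam_os, lam_pfs, gam_os, gam_pfs, comp_costs, comp_meds,
                      pp_cost, ae_cost, ae_dis, u_pf, u_pd, scen_arm,
                      cap = Inf, pm = 1) {
    pf <- rep(1, n); pd <- rep(0, n); dead <- rep(0, n)
    cost <- ae_cost
    qaly <- -ae_dis
    ly <- numeric(n)
    dur_rates <- lapply(comp_meds, function(m) log(2) / m)
    admin_comp <- which.max(vapply(comp_meds, mean, numeric(1)))
    for (i in seq_len(nc)) {
      a <- (i - 1) * dm; b <- i * dm; mid <- (a + b) / 2
      hbg <- background_hazard_monthly(life_table,
                                       settings$start_age + mid / 12)
      post <- scen_arm && a >= sw
      if (!post) {
        h_os <- lam_os * (b^gam_os - a^gam_os) / dm
        h_pfs <- lam_pfs * (b^gam_pfs - a^gam_pfs) / dm
      } else {
        h_os <- switch(mode, extrapolate = lam_os * (b^gam_os - a^gam_os) / dm,
                       optimistic = 0, pessimistic = h_ex)
        h_pfs <- if (mode == "optimistic" && stops_prog) 0 else
          lam_pfs * (b^gam_pfs - a^gam_pfs) / dm
      }
      p_death <- 1 - exp(-(h_os + hbg) * dm)
      p_exit <- 1 - exp(-(h_pfs + hbg) * dm)
      p_prog <- pmax(0, p_exit - p_death)
      pf2 <- pf * (1 - p_death - p_prog)
      pd2 <- pd * (1 - p_death) + pf * p_prog
      dead2 <- 1 - pf2 - pd2
      mpf <- (pf + pf2) / 2; mpd <- (pd + pd2) / 2
      alive <- mpf + mpd
      df <- (1 + settings$discount_rate)^(-mid / 12)
      cure_off <- post && mode == "optimistic" && stops_ther
      drug_off <- cure_off || mid >= cap
      cc <- alive * (d$cost_imaging_6wk / 2 + d$cost_other_weekly * 3) * sc +
        (dead2 - dead) * d$cost_eol
      if (!drug_off) {
        on_anchor <- NULL
        for (j in seq_along(comp_costs)) {
          occ <- exp(-dur_rates[[j]] * mid) * alive
          cc <- cc + occ * comp_costs[[j]] * pm * sc
          if (j == admin_comp) on_anchor <- occ
        }
        cc <- cc + on_anchor * d$cost_admin * sc
        if (societal) cc <- cc + on_anchor * (d$cost_patient_time +
                                                d$cost_travel) * sc
      }
      if (!cure_off) cc <- cc + mpd * pp_cost * sc
      if (societal) cc <- cc + alive * d$cost_caregiver_cycle * sc
      cost <- cost + cc * df
      qaly <- qaly + (mpf * u_pf + mpd * u_pd) * dy * df
      ly <- ly + alive * dy * df
      pf <- pf2; pd <- pd2; dead <- dead2
    }
    tibble(cost = cost, qaly = qaly, ly = ly)
  }

  ab <- one_arm(lam_os_ab, lam_pfs_ab, gam_os, gam_pfs,
                comp_costs = list(d$cost_atezo,
                                  d$cost_bev_ref * (d$weight_kg / 70) *
                                    (d$bev_dose_mg_kg / 15)),
                comp_meds = list(d$duration_atezo_median,
                                 d$duration_bev_median),
                pp_cost = d$cost_pp_ab, ae_cost = ae_cost_ab,
                ae_dis = ae_dis_ab, u_pf = d$util_pf_ab, u_pd = d$util_pd,
                scen_arm = !is.null(scenario), cap = cap_ab, pm = price_mult)
  sor <- one_arm(d$weibull_os_rate, d$weibull_pfs_rate, gam_os, gam_pfs,
                 comp_costs = list(d$cost_sorafenib),
                 comp_meds = list(d$duration_sor_median),
                 pp_cost = d$cost_pp_sor, ae_cost = ae_cost_sor,
                 ae_dis = ae_dis_sor, u_pf = d$util_pf_sor, u_pd = d$util_pd,
                 scen_arm = FALSE)
  list(ab = ab, sor = sor)
}
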