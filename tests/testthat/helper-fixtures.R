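# shared fixtures: survival laws, life tables, and a microsimulation oracle

sor_os_law <- function() parametric_survival("weibull", rate = 0.027, shape = 1.286)
sor_pfs_law <- function() parametric_survival("weibull", rate = 0.093, shape = 1.312)

zero_life_table <- function() tibble::tibble(age = 18:110, qx = 0)

# Independent individual-level oracle: simulates subject paths with the same
# per-cycle transition probabilities and accrues life-years/QALYs with the
# same half-cycle discounted formula as the cohort engine.
microsim_oracle <- function(strategy, settings, transitions, n_subjects,
                            seed = 1L) {
  set.seed(seed)
  state <- rep.int(1L, n_subjects)  # 1 = PF, 2 = PD, 3 = dead
  ly <- 0; qaly <- 0
  dy <- settings$cycle_months / 12
  for (i in seq_len(settings$n_cycles)) {
    tr <- transitions[i, ]
    u <- runif(n_subjects)
    alive <- state != 3L
    new_state <- state
    new_state[alive & u < tr$p_death] <- 3L
    promote <- alive & state == 1L & u >= tr$p_death &
      u < tr$p_death + tr$p_prog
    new_state[promote] <- 2L
    occ0 <- c(mean(state == 1L), mean(state == 2L))
    occ1 <- c(mean(new_state == 1L), mean(new_state == 2L))
    m <- (occ0 + occ1) / 2
    df <- (1 + settings$discount_rate)^(-((tr$t0 + tr$t1) / 2) / 12)
    ly <- ly + sum(m) * dy * df
    qaly <- qaly + (m[1] * strategy$utility_pf +
                      m[2] * strategy$utility_pd) * dy * df
    state <- new_state
  }
  ae <- ae_burden(strategy)
  list(life_years = ly, qalys = qaly - ae$ae_disutility)
}

# parameter table with every distribution degenerate at its base value
degenerate_parameters <- function() {
  dplyr::mutate(default_parameters(), dist = "fixed")
}
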