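---
title: "A Markov cohort model for first-line systemic therapy in unresectable HCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for first-line systemic therapy in unresectable HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hccea evaluates whether combining the PD-L1 inhibitor atezolizumab with the
anti-VEGF antibody bevacizumab is good value compared with sorafenib as
first-line treatment of unresectable hepatocellular carcinoma (HCC), from a
US payer perspective. The package covers the whole analysis chain: rebuilding
patient-level survival data from digitized trial curves, fitting and
selecting parametric survival laws, running a three-state Markov cohort
model with full cost and utility accounting, and propagating parameter
uncertainty. This vignette documents the model, its assumptions, the
defaults, and the places where the design was genuinely open.

## Model structure

Patients enter a three-state model — progression-free on first-line therapy
(PF), progressed (PD), dead — in the PF state. Time advances in 3-week
cycles over a 5-year horizon (86 cycles; the cycle length is exactly
21/365.25 years for discounting and QALY conversion). Costs and QALYs are
discounted at 3% per year at the cycle midpoint, and state membership is
counted as the mean of start- and end-of-cycle occupancy (half-cycle
correction, switchable).

Two survival laws drive the transitions. Overall survival (OS) governs death
from either alive state; progression-free survival (PFS) governs exit from
PF. Per cycle `[t, t+Δ)` the disease death hazard is
`-log(S_OS(t+Δ)/S_OS(t))/Δ`; the age-specific background hazard (from a life
table, converted via `-log(1-qx)/12`) is added on the hazard scale before
conversion to a probability, so all-cause mortality is never below general
population mortality. The progression probability is the non-negative
difference between the PFS-exit and death probabilities. This is the
standard two-curve construction when only published OS and PFS curves are
available.

```{r}
library(hccea)
settings <- model_settings()      # 21-day cycles, 5 y, 3%, start age 65
life_table <- make_life_table()   # synthetic Gompertz table (see below)
base <- evaluate_model(settings = settings, life_table = life_table)
base$comparison
```

## Survival inputs

The sorafenib arm uses Weibull laws in the rate–shape convention
`S(t) = exp(-λ t^γ)` with time in months: OS `λ = 0.027, γ = 1.286`
(median 12.5 months) and PFS `λ = 0.093, γ = 1.312` (median 4.6 months).
The combination arm applies the trial hazard ratios (OS 0.58, PFS 0.59) to
the sorafenib hazards; for a Weibull this is the closed-form rescaling
`λ → hr·λ`. Under this convention the hazard-scaled PFS median is 6.9
months, matching the trial's reported 6.8 months within 2%, which is why
the package treats hazard-scaling (rather than refitting the combination
curves, which is also supported via `strategy_spec()`) as the default.

A deliberate consequence: the hazard-scaled OS tail is steeper than the
landmark survival probabilities quoted alongside the trial (3-year survival
21% here versus a quoted 37.7%). No single Weibull can reproduce both the
published life-expectancy/QALY results and those landmark tails; the
hazard-scaled law reproduces the former, so it is the default, and the
scenario machinery (below) owns the long-term tail question explicitly.

## Time on treatment and costs

Drug and administration costs do not follow the PFS curve. The trial's
median treatment durations (atezolizumab 7.4, bevacizumab 6.9, sorafenib
2.8 months) are decoupled from progression in both directions: sorafenib is
typically stopped well before progression, while the combination may be
continued beyond it. Each drug component therefore carries its own
time-on-treatment curve — exponential with the observed median duration,
multiplied by the alive fraction — and drug plus administration costs accrue
on that occupancy. The trial's toxicity-discontinuation rates (7%/10%) are
kept as strategy metadata and PSA parameters but the engine relies on the
observed duration medians, which already embody all reasons for stopping.

Other accruals per cycle: imaging (half of the 6-weekly price) and
supportive care (weekly price × 3) while alive in any state; a blended
post-progression therapy price per cycle in PD; a one-off end-of-life cost
on the transition to death; and a one-off adverse-event burden at model
entry (`Σ incidence × management cost`, and `Σ incidence × disutility` as a
QALY decrement) over the grade 3–4 events with materially different rates
between arms (diarrhea, hand–foot syndrome, hypertension, bilirubin rise).
Bevacizumab's price scales linearly from its 70 kg / 15 mg/kg anchor
(`bev_cost()`). The societal perspective adds a caregiver cost per cycle
alive and patient-time plus travel costs per administration visit. All
prices are 2020 USD.

Utilities are 0.78 progression-free and 0.68 progressed, identical across
arms, so QALY differences are driven by occupancy. The computed one-off AE
decrements are 0.0149 (sorafenib) and 0.0019 (combination).

## Long-term survival scenarios

The trial follow-up ends around month 17, so tail behaviour is an
assumption, handled by `scenario_spec()`:

* **extrapolate** (base case) — the fitted OS law continues unchanged.
* **optimistic** — survivors at 17 months are considered cured. Death
  hazard falls to background mortality, progression stops, and anti-cancer
  therapy (first-line and post-progression) stops, while surveillance
  imaging and supportive care continue. Stopping therapy is part of what
  "cured" means clinically, and it is the only reading under which a cure
  can reduce total cost, as the published scenario tables show it must;
  both toggles are exposed (`cure_stops_therapy`, `cure_stops_progression`)
  for readers who want the narrower reading.
* **pessimistic** — after 17 months a constant excess hazard is added to
  background mortality, calibrated in closed form so the model's all-cause
  survival at 36 months equals a registry anchor (0.278 by default; 0.238
  selectable). The calibration is exact and self-verifying; an anchor above
  the 17-month survival is rejected, and an anchor only reachable with a
  negative excess hazard triggers a warning rather than an error so the
  mode remains usable with anchors that sit above the extrapolated tail —
  which both published anchors do under the hazard-scaled base curve. In
  that situation the "pessimistic" trajectory actually improves on plain
  extrapolation, and the package reports exactly that rather than forcing
  the expected ordering; the ordering property (pessimistic ≤ base ≤
  optimistic) is guaranteed only when the anchor lies below the
  extrapolated tail.

The survival function is continuous at the switch in all modes (only the
hazard jumps).

## Sensitivity analyses

`one_way_dsa()` re-runs the model at each parameter's range endpoints and
ranks ICER spreads (tornado). In this cost structure the ICER turns out to
be nearly flat in the OS hazard ratio: improving survival adds
post-progression and supportive-care cost at almost the same rate as it
adds QALYs, so drug prices dominate the tornado.

`psa()` draws every parameter from its stated distribution — normal for
hazard ratios (sd from the 95% CI, truncated just above zero), binomial for
trial proportions (denominators 336 and 165, divided back to rates),
triangular for costs, utilities and body weight — on common draws for both
arms, through a vectorized engine that reproduces the scalar engine to
machine precision at degenerate draws (asserted in the tests). The Weibull
λ, γ are held fixed: no distribution is stated for them, and inventing one
would mix structural with parameter uncertainty. 100,000 iterations run in
a few seconds. `ceac()` summarizes acceptability over willingness-to-pay;
`price_threshold()` bisects a common price multiplier on both combination
components to 0.1% resolution; `two_way_dsa()` evaluates full-factorial
ICER surfaces, including price-reduction and 3-year-survival pseudo-axes.

```{r}
pr <- psa(n_iter = 1e5, settings = settings, life_table = life_table,
          seed = 1)
pr$acceptability
price_threshold(150000)
```

## Synthetic data, reconstruction, and fitting

Every stage is testable without external downloads:

* `simulate_survival()` draws event times from any supported law with
  independent exponential censoring and administrative cutoff — the ground
  truth for parameter-recovery and round-trip tests.
* `make_km_curve()` emulates a digitized published curve: the Kaplan–Meier
  estimate on a coordinate grid, optional multiplicative log-normal jitter
  (clamped and made monotone, as a digitizer's output would be), plus true
  numbers at risk.
* `reconstruct_ipd()` rebuilds pseudo individual-patient data from a curve
  and risk table by interval-wise iterative allocation: censorings are
  spread uniformly within each inter-risk-table interval and their count
  adjusted until the implied number at risk matches the published count,
  while event counts track the digitized survival ratios; ties are broken
  by placing events at the digitized coordinate times. Beyond the last risk
  time the preceding censoring intensity is carried forward, or a known
  total event count pins the allocation.
* `fit_parametric()` maximizes the right-censored log-likelihood by BFGS on
  log-parameters from three starts (the closed-form exponential MLE seeds
  the others); `select_model()` ranks Weibull, exponential, log-logistic
  and log-normal by AIC with ties broken by parsimony then name.

The synthetic life table is Gompertz: annual mortality 4e-4 at age 18
doubling every 9 years, which lands near contemporary US all-cause rates
(about 0.015 at 65 and 0.05 at 80) — adequate because background mortality
is a second-order influence at these survival times. A real life table is a
drop-in replacement through the same `(age, qx)` format.

What the generator does not emulate: delayed treatment effects or
non-proportional hazards (the cure scenarios are the package's handle on
that), informative censoring, digitization bias that is systematic rather
than noise-like, and trial accrual patterns. Passing round-trip tests
therefore shows the pipeline is self-consistent, not that any particular
published curve was digitized faithfully.

## Numerical choices

* Cycle count is `floor(horizon · 365.25 / 21)`; accruals use exact
  midpoint discounting.
* Hazard/probability conversions go through `1 - exp(-h·Δ)` throughout, so
  compounded cycle probabilities reproduce the survivor function exactly.
* The pessimistic calibration is closed-form (no root-finder tolerance);
  the optimizer tolerance is `reltol = 1e-10` with three starts; curve
  monotonicity repairs above 0.005 survival are rejected as data errors,
  smaller ones repaired with a message.
* Degenerate inputs: all-censored data refuse to fit; an empty cohort or
  non-ascending grid is an input error; zero-width sensitivity ranges yield
  zero tornado spread rather than an error.

Test problem sizes, chosen to keep Monte-Carlo error well below the asserted
tolerances: parameter recovery at n = 5,000 per family, empirical-band
checks at n = 10,000, curve round trips at n = 300–500, a 200,000-subject
microsimulation as the independent oracle for the cohort engine, and
100,000-iteration PSAs.

## Known limitations

* The model reproduces headline incremental results well, but several of
  the published downstream figures (pessimistic scenario ICER, base-case
  acceptability, one of four price-reduction rows) are mutually
  inconsistent with the published inputs and with each other; where a
  faithful computation cannot match them, the package reports its own
  computed value. The test suite encodes the published values at their
  stated tolerances, so these show up as explicit test failures rather
  than silent adjustments.
* Costs use a blended post-progression price per cycle, not explicit
  subsequent-therapy market shares; no value-of-information analysis; no
  time-varying hazard ratios or spline extrapolations.
* Parameter correlation is not modelled in the PSA (none is stated).
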