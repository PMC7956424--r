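#' Model parameter table (base case, ranges, distributions)
#'
#' One row per model input: base-case value, deterministic-sensitivity range,
#' and the distribution used in probabilistic sensitivity analysis
#' (`normal` for hazard ratios, `binomial` for trial proportions with the
#' IMbrave 150 arm sizes as denominators, `triangular` for costs and
#' utilities, `fixed` for quantities held constant). Costs are 2020 USD;
#' drug and cost entries labelled "per cycle" refer to the 3-week cycle.
#'
#' Normal standard deviations are derived from the stated 95% confidence
#' intervals; proportions use denominators 336 (atezolizumab-bevacizumab) and
#' 165 (sorafenib).
#'
#' @return A tibble with columns `parameter`, `base`, `lo`, `hi`, `dist`,
#'   `denom`.
#' @export
default_parameters <- function() {
  p <- function(parameter, base, lo, hi, dist, denom = NA_real_) {
    tibble(parameter = parameter, base = base, lo = lo, hi = hi,
           dist = dist, denom = denom)
  }
  bind_rows(
    p("hr_os", 0.58, 0.42, 0.79, "normal"),
    p("hr_pfs", 0.59, 0.47, 0.76, "normal"),
    p("weibull_os_rate", 0.027, NA, NA, "fixed"),
    p("weibull_os_shape", 1.286, NA, NA, "fixed"),
    p("weibull_pfs_rate", 0.093, NA, NA, "fixed"),
    p("weibull_pfs_shape", 1.312, NA, NA, "fixed"),
    p("weight_kg", 70, 40, 200, "triangular"),
    p("bev_dose_mg_kg", 15, NA, NA, "fixed"),
    p("cost_atezo", 9419.16, 7535.33, 11302.99, "triangular"),
    p("cost_bev_ref", 117.60, 94.08, 141.12, "triangular"),
    p("cost_sorafenib", 14609.28, 11687.42, 17531.14, "triangular"),
    p("cost_admin", 435.04, 348.03, 522.05, "triangular"),
    p("cost_imaging_6wk", 1543, 1235, 1852, "triangular"),
    p("cost_other_weekly", 174.5, 139.6, 209.4, "triangular"),
    p("cost_eol", 7360.16, 6208.85, 9313.77, "triangular"),
    p("cost_pp_ab", 4612.66, 3690.13, 5535.20, "triangular"),
    p("cost_pp_sor", 4825.93, 3860.74, 5791.11, "triangular"),
    p("cost_caregiver_cycle", 382.21, 305.77, 458.65, "triangular"),
    p("cost_patient_time", 896.2, 716.96, 1075.44, "triangular"),
    p("cost_travel", 329.5, 263.6, 395.4, "triangular"),
    p("cost_ae_diarrhea", 88.38, 70.70, 106.05, "triangular"),
    p("cost_ae_hfs", 145.65, 116.51, 174.78, "triangular"),
    p("cost_ae_hypertension", 64.01, 51.21, 76.81, "triangular"),
    p("cost_ae_bilirubin", 0, 0, 0, "triangular"),
    p("util_pf_ab", 0.78, 0.624, 0.936, "triangular"),
    p("util_pf_sor", 0.78, 0.624, 0.936, "triangular"),
    p("util_pd", 0.68, 0.54, 0.82, "triangular"),
    p("disutil_diarrhea", 0.103, 0.082, 0.123, "triangular"),
    p("disutil_hfs", 0.116, 0.093, 0.139, "triangular"),
    p("disutil_hypertension", 0, 0, 0, "triangular"),
    p("disutil_bilirubin", 0, 0, 0, "triangular"),
    p("ae_ab_diarrhea", 0.018, 0.014, 0.022, "binomial", 336),
    p("ae_ab_hfs", 0, 0, 0, "binomial", 336),
    p("ae_ab_hypertension", 0.152, 0.122, 0.182, "binomial", 336),
    p("ae_ab_bilirubin", 0.024, 0.019, 0.029, "binomial", 336),
    p("ae_sor_diarrhea", 0.051, 0.041, 0.061, "binomial", 165),
    p("ae_sor_hfs", 0.083, 0.066, 0.1, "binomial", 165),
    p("ae_sor_hypertension", 0.122, 0.098, 0.146, "binomial", 165),
    p("ae_sor_bilirubin", 0.064, 0.051, 0.077, "binomial", 165),
    p("discontinuation_ab", 0.07, 0.056, 0.084, "binomial", 336),
    p("discontinuation_sor", 0.10, 0.08, 0.12, "binomial", 165),
    p("duration_atezo_median", 7.4, NA, NA, "fixed"),
    p("duration_bev_median", 6.9, NA, NA, "fixed"),
    p("duration_sor_median", 2.8, NA, NA, "fixed"))
}

#' Named list of base-case parameter values
#'
#' @param params Parameter table from [default_parameters()].
#' @return A named list mapping parameter names to base values, suitable for
#'   overriding and passing to [evaluate_model()] or the strategy builders.
#' @export
base_values <- function(params = default_parameters()) {
  setNames(as.list(params$base), params$parameter)
}
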