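#' Plot a Markov trace
#'
#' State occupancy over time for one cohort run.
#'
#' @param object A `cohort_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_result
#' @export
autoplot.cohort_result <- function(object, ...) {
  long <- object$trace %>%
    select("t1", "pf", "pd", "dead") %>%
    tidyr::pivot_longer(c("pf", "pd", "dead"), names_to = "state",
                        values_to = "occupancy") %>%
    mutate(state = factor(.data$state, levels = c("pf", "pd", "dead"),
                          labels = c("progression-free", "progressed",
                                     "dead")))
  ggplot2::ggplot(long, ggplot2::aes(.data$t1, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (months)", y = "state occupancy",
                  colour = NULL, title = object$strategy) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' @param object A tornado tibble from [one_way_dsa()].
#' @param top Number of parameters to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hccea_tornado
#' @export
autoplot.hccea_tornado <- function(object, top = 12, ...) {
  d <- object %>%
    filter(!.data$failed, .data$spread > 0) %>%
    head(top) %>%
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_lo, xend = .data$icer_hi,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve and PSA scatter
#'
#' @param object A `psa_result`.
#' @param type `"ceac"` or `"scatter"` (incremental cost-effect plane).
#' @param wtps WTP grid for the CEAC.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, type = c("ceac", "scatter"),
                                wtps = seq(0, 3e5, by = 5e3), ...) {
  type <- match.arg(type)
  if (type == "ceac") {
    cc <- ceac(object, wtps)
    ggplot2::ggplot(cc, ggplot2::aes(.data$wtp, .data$probability)) +
      ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
      ggplot2::scale_y_continuous(limits = c(0, 1)) +
      ggplot2::labs(x = "willingness to pay (USD/QALY)",
                    y = "probability cost-effective") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$draws,
                    ggplot2::aes(.data$delta_qalys, .data$delta_cost)) +
      ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "incremental QALYs", y = "incremental cost (USD)") +
      ggplot2::theme_minimal()
  }
}

#' Survival-curve overlay for fitted and reference laws
#'
#' @param dists Named list of [parametric_survival()] objects.
#' @param horizon Months to plot.
#' @return A ggplot object.
#' @export
plot_survival <- function(dists, horizon = 60) {
  grid <- seq(0, horizon, length.out = 241)
  d <- purrr::imap(dists, function(dd, nm)
    tibble(time = grid, survival = survival_at(dd, grid), law = nm)) %>%
    purrr::list_rbind()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                  colour = .data$law)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (months)", y = "S(t)", colour = NULL) +
    ggplot2::theme_minimal()
}
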