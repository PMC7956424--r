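# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_hccea <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "hccea_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE, finite = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (!finite || is.finite(x)) && x >= lower && x <= upper &&
    (allow_zero || x != 0)
  if (!ok) {
    stop_hccea(
      sprintf("`%s` must be a single number in [%s, %s]; got %s",
              name, format(lower), format(upper),
              paste(format(x), collapse = ", ")),
      class = "hccea_domain_error")
  }
  invisible(x)
}

#' Draw from a triangular distribution
#'
#' Standard three-parameter triangular sampler used for cost and utility
#' uncertainty in probabilistic sensitivity analysis.
#'
#' @param n Number of draws.
#' @param min,mode,max Triangle vertices; `min <= mode <= max`.
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' summary(rtriangular(1000, 40, 70, 200))
#' @export
rtriangular <- function(n, min, mode, max) {
  if (!(min <= mode && mode <= max)) {
    stop_hccea("triangular distribution requires min <= mode <= max",
               class = "hccea_domain_error")
  }
  if (max == min) return(rep(mode, n))
  u <- runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# months in one cycle given cycle length in days
cycle_months <- function(cycle_length_days) cycle_length_days / 365.25 * 12
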