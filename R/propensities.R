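#' Event propensities of the current population state
#'
#' Division propensity of genotype X is `f_X * max(0, 1 - N/K) * n_X`
#' (logistic crowding; the factor is clamped at 0 for `N >= K`, so the
#' capacity acts as a reflecting ceiling for births), death propensity is
#' `g_X * n_X`. This is the exact rate table the event-driven simulator
#' uses; it is exposed mainly for inspection and testing.
#'
#' @param counts Named numeric vector `c(S=, R=, C=)` of genotype counts.
#' @param rates An [env_rates()] (the environment currently in force).
#' @param params A [model_params()] (supplies `K`).
#' @return Named numeric vector with elements `div_S, div_R, div_C,
#'   death_S, death_R, death_C`.
#' @examples
#' p <- model_params(K = 1000)
#' propensities(c(S = 900, R = 0, C = 0), p$rates_no_drug, p)
#' @export
propensities <- function(counts, rates, params) {
  stopifnot(all(c("S", "R", "C") %in% names(counts)))
  counts <- counts[c("S", "R", "C")]
  if (any(counts < 0)) stop("counts must be >= 0")
  N <- sum(counts)
  L <- max(0, 1 - N / params$K)
  div <- rates$fitness * L * counts
  death <- rates$death * counts
  c(div_S = unname(div[["S"]]), div_R = unname(div[["R"]]),
    div_C = unname(div[["C"]]),
    death_S = unname(death[["S"]]), death_R = unname(death[["R"]]),
    death_C = unname(death[["C"]]))
}
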