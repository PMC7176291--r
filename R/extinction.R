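# Thomas algorithm for a tridiagonal system
#   a[i] x[i-1] + b[i] x[i] + c[i] x[i+1] = d[i],  i = 1..n
# (a[1] and c[n] ignored).  O(n); the birth-death systems solved here are
# diagonally dominant, so no pivoting is needed.
.tridiag_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (i in seq_len(n - 1) + 1) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in rev(seq_len(n - 1))) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Mean extinction time of a pure-death population
#'
#' With divisions fully stopped (perfect biostatic drug) the population
#' is a pure death process; the mean time for `N` individuals with death
#' rate `g` to reach zero is the harmonic sum
#' `tauS = (1/g) * sum_{i=1}^{N} 1/i ~ log(N)/g`.
#'
#' @param N Starting size (integer `>= 0`; 0 returns 0).
#' @param g Death rate, `> 0`.
#' @return Mean extinction time.
#' @examples
#' tau_pure_death(900, 0.1) # ~73.8
#' @export
tau_pure_death <- function(N, g) {
  stopifnot(N >= 0, g > 0)
  if (N == 0) return(0)
  # summing small terms first keeps the harmonic sum stable
  sum(1 / rev(seq_len(N))) / g
}

#' Mean extinction time of the logistic birth-death chain
#'
#' First-passage time to 0 of the chain with birth rates
#' `lambda_n = f' n max(0, 1 - n/K)` and death rates `mu_n = g' n`,
#' starting from `N0`. The state space is `{0..K}` (births are impossible
#' at `K` under the clamped logistic rate, so the chain is finite without
#' further approximation); the mean absorption times solve the standard
#' tridiagonal system `(lambda_n + mu_n) tau_n = 1 + lambda_n tau_{n+1} +
#' mu_n tau_{n-1}` with `tau_0 = 0`, solved in O(K).
#'
#' The result obeys the scaling `tauS(f', g', K) = Phi(R) / g'` with
#' `R = (g' - f')/g'`: at fixed drug-strength ratio, a faster-killing
#' drug shortens the extinction time proportionally.
#'
#' @param f_prime,g_prime Division and death rates with drug (`g' > 0`).
#' @param K Carrying capacity (the truncation size).
#' @param N0 Starting size, `1 <= N0 <= K`.
#' @return Mean extinction time from `N0`.
#' @export
tau_birth_death_logistic <- function(f_prime, g_prime, K, N0) {
  stopifnot(g_prime > 0, f_prime >= 0, N0 >= 1, N0 <= K)
  K <- as.integer(.round_half_up(K))
  n <- seq_len(K)
  lambda <- f_prime * n * pmax(0, 1 - n / K)
  mu <- g_prime * n
  tau <- .tridiag_solve(a = -mu, b = lambda + mu, c = -lambda,
                        d = rep(1, K))
  tau[as.integer(.round_half_up(N0))]
}

#' Critical period for single-phase eradication
#'
#' When the half-period exceeds the mean extinction time `tauS` of the
#' sensitive population under drug, one drug phase suffices to eradicate
#' a resistance-free population; the extinction probability jumps up at
#' `T* = 2 tauS`. `tauS` is evaluated from the drug-free equilibrium size
#' `N0 = round(K (1 - gS/fS))`.
#'
#' @param params A [model_params()].
#' @return The threshold period `T*`.
#' @export
solve_T_threshold <- function(params) {
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  fp <- params$rates_drug$fitness[["S"]]
  gp <- params$rates_drug$death[["S"]]
  N0 <- .round_half_up(equilibrium_size(fS, gS, params$K))
  tau <- if (fp == 0) tau_pure_death(N0, gp)
         else tau_birth_death_logistic(fp, gp, params$K, N0)
  2 * tau
}

#' Drug strength needed for extinction within a half-period
#'
#' Solves `tauS(R) = T/2` for the drug-strength ratio `R`: below the root
#' a single drug phase is too short on average and resistance is
#' predicted to take over; above it, the first drug phase kills. Rates
#' are parameterized per the fixed conventions (see [params_at_ratio()]):
#' biocidal `f'S = fS`, `g'S = fS/(1-R)`; biostatic `g'S = gS`,
#' `f'S = gS (1-R)`. `tauS` is monotone decreasing in `R`, so the root in
#' the bracket `(-0.9, 0.9)` is unique; bisection to `|dR| < 1e-4`.
#'
#' @param period Alternation period `T`.
#' @param K Carrying capacity.
#' @param params A [model_params()] supplying the no-drug rates.
#' @param mode `"biostatic"` or `"biocidal"`.
#' @param bracket Search interval for `R`.
#' @return The critical ratio `R*`.
#' @export
solve_R_threshold_small_period <- function(period, K, params,
                                           mode = c("biostatic", "biocidal"),
                                           bracket = c(-0.9, 0.9)) {
  mode <- match.arg(mode)
  stopifnot(period > 0)
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  N0 <- .round_half_up(equilibrium_size(fS, gS, K))
  tau_at <- function(R) {
    pr <- params_at_ratio(R, params, mode)
    tau_birth_death_logistic(pr$rates_drug$fitness[["S"]],
                             pr$rates_drug$death[["S"]], K, N0)
  }
  g <- function(R) tau_at(R) - period / 2
  lo <- bracket[1]; hi <- bracket[2]
  glo <- g(lo); ghi <- g(hi)
  if (is.nan(glo) || is.nan(ghi) || sign(glo) == sign(ghi))
    stop("no sign change of tauS(R) - T/2 on bracket [", lo, ", ", hi,
         "]; tauS(", lo, ") - T/2 = ", glo, ", tauS(", hi, ") - T/2 = ", ghi)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(glo)) { lo <- mid; glo <- g(mid) } else hi <- mid
  }
  (lo + hi) / 2
}
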