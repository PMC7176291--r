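# round-half-up (round() does banker's rounding; the contract says ties
# round up -- only matters for tiny K)
.round_half_up <- function(x) floor(x + 0.5)

#' Deterministic equilibrium population size
#'
#' Setting the logistic birth rate `f (1 - N/K)` equal to the death rate
#' `g` gives `N = K (1 - g/f)`, the size a growing population settles at.
#'
#' @param f Division rate, must exceed `g`.
#' @param g Death rate, `>= 0`.
#' @param K Carrying capacity.
#' @return The equilibrium size (a real number; round for counts).
#' @examples
#' equilibrium_size(1, 0.1, 1000) # 900
#' @export
equilibrium_size <- function(f, g, K) {
  if (g < 0) stop("g must be >= 0")
  if (f <= g) stop("no positive equilibrium: need f > g")
  K * (1 - g / f)
}

#' Deterministic decay of the sensitive population under drug
#'
#' Closed-form solution of `dS/dt = f' S (1 - S/K) - g' S` with
#' `S(0) = S0`. For a perfect biostatic (`f' = 0`) this is pure
#' exponential decay `S0 exp(-g' t)`; in general, with `a = f' - g'` and
#' `b = f'/K`, `S(t) = a S0 e^{at} / (a + b S0 (e^{at} - 1))` (and
#' `S0 / (1 + b S0 t)` at the MIC, `a = 0`).
#'
#' @param f_prime,g_prime S division and death rates with drug.
#' @param K Carrying capacity.
#' @param S0 Initial size; defaults to the drug-free equilibrium
#'   `K (1 - gS/fS)` for the baseline `fS = 1`, `gS = 0.1`.
#' @return An object of class `deterministic_decay` (an evaluator used by
#'   [s_of_t()], [n_div()] and the rescue formulas).
#' @export
deterministic_decay <- function(f_prime, g_prime, K,
                                S0 = equilibrium_size(1, 0.1, K)) {
  stopifnot(f_prime >= 0, g_prime >= 0, K >= 1, S0 >= 0)
  structure(list(f_prime = f_prime, g_prime = g_prime, K = K, S0 = S0),
            class = "deterministic_decay")
}

#' Decay from a parameter set
#'
#' Convenience constructor: drug-phase S rates and the drug-free
#' equilibrium starting size, read off a [model_params()].
#'
#' @param params A [model_params()].
#' @return A [deterministic_decay()].
#' @export
decay_from_params <- function(params) {
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  deterministic_decay(params$rates_drug$fitness[["S"]],
                      params$rates_drug$death[["S"]],
                      params$K,
                      S0 = equilibrium_size(fS, gS, params$K))
}

#' Evaluate the deterministic sensitive trajectory
#'
#' @param decay A [deterministic_decay()].
#' @param t Time(s), `>= 0` (vectorized).
#' @return `S(t)`, same length as `t`.
#' @export
s_of_t <- function(decay, t) {
  stopifnot(inherits(decay, "deterministic_decay"))
  if (any(t < 0)) stop("t must be >= 0")
  S0 <- decay$S0
  if (S0 == 0) return(rep(0, length(t)))
  fp <- decay$f_prime; gp <- decay$g_prime
  if (fp == 0) return(S0 * exp(-gp * t))
  a <- fp - gp
  b <- fp / decay$K
  if (a == 0) return(S0 / (1 + b * S0 * t))
  e <- exp(a * t)
  a * S0 * e / (a + b * S0 * (e - 1))
}

# closed-form running integral of S(u) du on [0, t] (vectorized);
# integral_s_inf() gives the t -> Inf limit (finite only for decaying S)
.integral_s <- function(decay, t) {
  S0 <- decay$S0
  if (S0 == 0) return(rep(0, length(t)))
  fp <- decay$f_prime; gp <- decay$g_prime
  if (fp == 0) return((S0 / gp) * (1 - exp(-gp * t)))
  a <- fp - gp
  b <- fp / decay$K
  if (a == 0) return(log1p(b * S0 * t) / b)
  # d/dt log(a + b S0 (e^{at} - 1)) = b S(t)
  log((a + b * S0 * (exp(a * t) - 1)) / a) / b
}

.integral_s_inf <- function(decay) {
  S0 <- decay$S0
  if (S0 == 0) return(0)
  fp <- decay$f_prime; gp <- decay$g_prime
  if (fp == 0) return(S0 / gp)
  a <- fp - gp
  if (a >= 0) return(Inf)
  log((a - fp * S0 / decay$K) / a) * decay$K / fp
}

# time at which S(t) first drops to `level` (used to truncate infinite
# horizons); Inf when S never decays to it
.decay_horizon <- function(decay, level = 1e-9) {
  S0 <- decay$S0
  if (S0 <= level) return(0)
  fp <- decay$f_prime; gp <- decay$g_prime
  if (fp == 0) return(log(S0 / level) / gp)
  a <- fp - gp
  if (a >= 0) return(Inf)
  # large-t tail S(t) ~ C e^{at}: invert, then refine by bisection
  upper <- log(S0 / level) / (-a) * 4 + 1
  while (s_of_t(decay, upper) > level) upper <- upper * 2
  stats::uniroot(function(tt) s_of_t(decay, tt) - level,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Expected number of divisions during the kill phase
#'
#' `N_div = integral_0^tauS f'S (1 - S(t)/K) S(t) dt`: the expected
#' number of division events in the decaying sensitive population between
#' drug addition and (mean) extinction. Each division carries a
#' resistance mutation with probability `mu1`, so `pRa = N_div * mu1` is
#' the probability that resistance arises *during* treatment. A perfect
#' biostatic has `f'S = 0` and hence `N_div = 0`: it fully prevents this
#' rescue route.
#'
#' The integrand uses the drug-phase division rate `f'S` (the integral
#' covers the drug phase; consistency demands `N_div = 0` when
#' `f'S = 0`).
#'
#' @param params A [model_params()].
#' @param tau_S Upper limit: the mean extinction time, normally from
#'   [tau_birth_death_logistic()]; pass `Inf` for the full-horizon
#'   variant.
#' @param decay Optional [deterministic_decay()]; defaults to
#'   [decay_from_params()].
#' @return Expected number of divisions (real, `>= 0`).
#' @export
n_div <- function(params, tau_S, decay = decay_from_params(params)) {
  stopifnot(tau_S > 0)
  fp <- decay$f_prime
  if (fp == 0) return(0)
  upper <- if (is.finite(tau_S)) tau_S else .decay_horizon(decay)
  f <- function(tt) {
    s <- s_of_t(decay, tt)
    fp * pmax(0, 1 - s / decay$K) * s
  }
  q <- stats::integrate(f, 0, upper, rel.tol = 1e-8, subdivisions = 500L)
  if (q$message != "OK") stop("quadrature failed: ", q$message)
  q$value
}
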