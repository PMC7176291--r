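#' Specification of a two-type Moran competition
#'
#' Fixed-size death-replacement dynamics: each individual dies at its
#' genotype's death rate and is immediately replaced by the offspring of
#' an individual chosen proportionally to fitness. With mutant count `j`
#' in a population of size `N`, the chain moves `j -> j+1` at rate
#' `g_res (N-j) * f_mut j / (f_mut j + f_res (N-j))` and `j -> j-1` at
#' rate `g_mut j * f_res (N-j) / (f_mut j + f_res (N-j))`. This timescale
#' reproduces both the fixation formulas used by the theory and the
#' mutant supply rate `N mu1 gS` at demographic equilibrium.
#'
#' @param N Population size, `>= 2`.
#' @param f_res,g_res Resident division and death rates.
#' @param f_mut,g_mut Mutant division and death rates.
#' @return An object of class `moran_spec`.
#' @export
moran_spec <- function(N, f_res, g_res, f_mut, g_mut) {
  stopifnot(N >= 2, f_res > 0, f_mut > 0, g_res > 0, g_mut > 0)
  structure(list(N = as.integer(.round_half_up(N)), f_res = f_res,
                 g_res = g_res, f_mut = f_mut, g_mut = g_mut),
            class = "moran_spec")
}

# step-bias ratio q = (down rate)/(up rate), constant in j
.moran_q <- function(spec) {
  (spec$f_res * spec$g_mut) / (spec$f_mut * spec$g_res)
}

#' Fixation probability of a single mutant (Moran model)
#'
#' With step-bias ratio `q = (f_res g_mut)/(f_mut g_res)` (reducing to
#' `f_res/f_mut` for equal death rates), a single mutant fixes with
#' probability `(1 - q)/(1 - q^N)`, and `1/N` in the neutral case
#' `q = 1`.
#'
#' @param spec A [moran_spec()].
#' @return Fixation probability in `(0, 1)`.
#' @examples
#' # resistant mutant (f = 0.9) under fast drug alternation (f~S = 0.5):
#' fixation_probability(moran_spec(800, 0.5, 0.1, 0.9, 0.1)) # ~0.444
#' @export
fixation_probability <- function(spec) {
  q <- .moran_q(spec)
  N <- spec$N
  if (q == 1) return(1 / N)
  lq <- N * log(q)
  # for q > 1 and huge N, (1-q)/(1-q^N) = (q-1) q^{-N} / (1 - q^{-N})
  if (lq > 700) return((q - 1) * exp(-lq))
  (1 - q) / (1 - q^N)
}

# h[j] = P(absorb at 0 before N | start j) for the constant-bias chain;
# returned as the two local ratios needed for the h-transform, computed
# stably (q^m can overflow for large N)
.h_ratios <- function(q, N, j) {
  m <- N - j
  if (q == 1) return(list(up = (m - 1) / m, down = (m + 1) / m))
  lg <- log(q)
  num_up <- expm1((m - 1) * lg); den <- expm1(m * lg)
  num_dn <- expm1((m + 1) * lg)
  if (!is.finite(den) || !is.finite(num_dn)) {
    # q > 1 and m log q overflows: ratios tend to 1/q * q = 1 exactly
    return(list(up = 1, down = 1))
  }
  list(up = q * num_up / den, down = num_dn / (q * den))
}

#' Sojourn decomposition of a single mutant lineage
#'
#' For a lineage founded by one mutant, computes the mean time
#' `tau_{R,i}` spent at each occupancy `i` in `1..N-1` before absorption,
#' the total lifetime `tau_d = sum_i tau_{R,i}`, and the conditional
#' occupancy distribution `pRc(i) = tau_{R,i} / tau_d` — the probability
#' that, at a uniformly random moment of its life, the lineage has `i`
#' copies. This is the distribution of the number of preexisting
#' resistant mutants at the moment drug is added, given at least one.
#'
#' Conditioning `"extinction"` (the default) restricts to lineages
#' destined for loss, via the Doob h-transform on the probability of
#' absorption at 0; `"none"` uses the unconditioned chain. For
#' deleterious mutants at realistic sizes the two are nearly identical.
#'
#' Sojourn times are the solution of the tridiagonal adjoint system
#' `Q^T s = -e_1` on the transient states (an O(N) solve; `N <= 1e4` by
#' contract).
#'
#' @param spec A [moran_spec()].
#' @param conditioning `"extinction"` or `"none"`.
#' @return A list of class `lineage_stats`: `tau_d`, `sojourn` (length
#'   `N-1`), `pRc` (normalized sojourn), `conditioning`.
#' @export
lineage_stats <- function(spec, conditioning = c("extinction", "none")) {
  conditioning <- match.arg(conditioning)
  N <- spec$N
  if (N > 1e4)
    stop("N > 1e4: dense sojourn solve refused by contract")
  j <- seq_len(N - 1)
  w <- spec$f_mut * j + spec$f_res * (N - j)
  lambda <- spec$g_res * (N - j) * spec$f_mut * j / w
  mu <- spec$g_mut * j * spec$f_res * (N - j) / w
  if (conditioning == "extinction") {
    q <- .moran_q(spec)
    for (i in j) {
      r <- .h_ratios(q, N, i)
      lambda[i] <- lambda[i] * r$up
      mu[i] <- mu[i] * r$down
    }
  }
  # adjoint (transpose) system: sub-diagonal lambda[i-1], super mu[i+1];
  # total exit rate is unchanged by the h-transform (h is harmonic)
  n <- N - 1
  a <- c(0, -lambda[seq_len(n - 1)])
  b <- lambda + mu
  cc <- c(-mu[seq_len(n - 1) + 1], 0)
  d <- c(1, rep(0, n - 1))
  s <- .tridiag_solve(a, b, cc, d)
  tau_d <- sum(s)
  structure(list(tau_d = tau_d, sojourn = s, pRc = s / tau_d,
                 conditioning = conditioning),
            class = "lineage_stats")
}

#' Probability that a resistant mutant preexists at drug addition
#'
#' In the rare-mutation regime (`K mu1 << 1`) resistant lineages arise at
#' rate `N mu1 gS` (mutation rate per division times the equilibrium
#' division flux) and each lives `tau_d` on average, so one is present at
#' a random moment with probability `pR = N mu1 gS tau_d`
#' (= `tau_d / t_app` with appearance time `t_app = 1/(N mu1 gS)`).
#'
#' @param N Population size.
#' @param mu1 Mutation probability per division.
#' @param gS Sensitive death rate (= per-capita division rate at
#'   equilibrium).
#' @param stats A [lineage_stats()] (or anything with `$tau_d`).
#' @return `min(1, N mu1 gS tau_d)`; warns if the cap binds or if
#'   `N mu1 > 0.1` (outside the rare-mutation regime).
#' @export
p_preexisting <- function(N, mu1, gS, stats) {
  if (N * mu1 > 0.1)
    warning("N*mu1 = ", N * mu1, " > 0.1: rare-mutation assumption strained")
  p <- N * mu1 * gS * stats$tau_d
  if (p > 1) {
    warning("pR capped at 1 (raw value ", signif(p, 4), ")")
    p <- 1
  }
  p
}

#' Mean waiting time for a resistant mutant that fixes
#'
#' `t_Ra = 1 / (N mu1 g_div p_fix)`: mutants arise at total rate
#' `N mu1 g_div` and each fixes with probability `p_fix`. The caller
#' supplies the regime-appropriate ingredients: under very fast
#' alternation `(N~, gS, p~SR)`; under constant sub-MIC drug
#' `(N', g'S, p'SR)`.
#'
#' @param N Population size.
#' @param mu1 Mutation probability per division.
#' @param g_div Per-capita division (= death) rate at the fixed size.
#' @param p_fix Fixation probability, e.g. [fixation_probability()].
#' @return Mean appearance time of the successful mutant; `Inf` if any
#'   factor is zero.
#' @export
appearance_fixation_time <- function(N, mu1, g_div, p_fix) {
  r <- N * mu1 * g_div * p_fix
  if (r <= 0) return(Inf)
  1 / r
}

#' Mean fitness-valley crossing time by tunneling
#'
#' Without drug, resistance (costly, `fR < fS`) plus compensation can
#' still fix spontaneously by stochastic tunneling; the mean waiting time
#' is `tau_V ~ (fS - fR)/(mu1 mu2 gS)`. Alternation periods with
#' `T/2 >> tau_V` therefore lose the race to spontaneous resistance even
#' before any drug is seen.
#'
#' @param params A [model_params()].
#' @return `tau_V` (time units).
#' @export
valley_crossing_time <- function(params) {
  fS <- params$rates_no_drug$fitness[["S"]]
  fR <- params$rates_no_drug$fitness[["R"]]
  gS <- params$rates_no_drug$death[["S"]]
  if (fS <= fR) stop("no fitness valley: need fS > fR")
  if (params$mu1 <= 0 || params$mu2 <= 0 || gS <= 0)
    stop("mu1, mu2 and gS must be > 0")
  (fS - fR) / (params$mu1 * params$mu2 * gS)
}
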