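#' Integrated net-death exponent of a resistant lineage
#'
#' `rho(t) = integral_0^t [gR - fR (1 - S(u)/K)] du`: the accumulated
#' difference between the death rate of a resistant cell and its division
#' rate while the sensitive background `S(u)` decays and frees up
#' carrying capacity. Early on (large `S`) the lineage is barely
#' supercritical; once `S` has collapsed, `rho` decreases linearly at
#' rate `fR - gR`. Evaluated in closed form (the running integral of
#' `S` has one for both decay branches).
#'
#' @param t Time(s), `>= 0` (vectorized).
#' @param decay A [deterministic_decay()] for the sensitive background.
#' @param fR,gR Resistant division and death rates.
#' @return `rho(t)`, same length as `t`.
#' @export
rho <- function(t, decay, fR, gR) {
  if (any(t < 0)) stop("t must be >= 0")
  (gR - fR) * t + (fR / decay$K) * .integral_s(decay, t)
}

# I(t0) = integral_{t0}^Inf e^{rho(u) - rho(t0)} du, the kernel of the
# extinction probabilities.  The integrand eventually decays like
# e^{-(fR-gR) u}; truncate where S has collapsed plus a generous tail
# window, add the exact exponential tail, and verify by doubling.
.survival_integral <- function(decay, fR, gR, t0 = 0) {
  stopifnot(fR > gR)
  rho0 <- rho(t0, decay, fR, gR)
  f <- function(u) exp(rho(u, decay, fR, gR) - rho0)
  horizon <- .decay_horizon(decay, level = 1e-9)
  upper <- max(t0, horizon) + 40 / (fR - gR)
  one_pass <- function(up) {
    q <- stats::integrate(f, t0, up, rel.tol = 1e-10, subdivisions = 1000L)
    if (q$message != "OK") stop("quadrature failed: ", q$message)
    # exact tail: for u > up, S ~ 0 so rho'(u) = gR - fR
    q$value + f(up) / (fR - gR)
  }
  v1 <- one_pass(upper)
  v2 <- one_pass(t0 + (upper - t0) * 2)
  if (abs(v2 - v1) > 1e-8 * abs(v2))
    stop("survival integral did not converge under horizon doubling")
  v2
}

#' Early-extinction probability of a preexisting resistant lineage
#'
#' A lineage of `i` resistant cells present at the moment of drug
#' addition dies out (rather than rescuing the population) with
#' probability `pRe(i) = [gR I / (1 + gR I)]^i` where
#' `I = integral_0^Inf e^{rho(u)} du` — the solved form of the
#' time-inhomogeneous branching process with the decaying sensitive
#' background feeding through the logistic term. The `i`-th power
#' expresses the independence of the `i` sub-lineages. With `S = 0`
#' throughout this reduces to the textbook constant-rate extinction
#' probability `(gR/fR)^i`.
#'
#' @param i Initial copy number(s), `>= 1` (vectorized).
#' @param decay A [deterministic_decay()] (use the drug-phase rates).
#' @param fR,gR Resistant division and death rates. If `fR <= gR` the
#'   lineage is subcritical even without competition and the probability
#'   is exactly 1.
#' @return Extinction probability/ies in `(0, 1]`.
#' @export
p_extinct_lineage <- function(i, decay, fR, gR) {
  stopifnot(all(i >= 1))
  if (fR <= gR) return(rep(1, length(i)))
  I <- .survival_integral(decay, fR, gR, t0 = 0)
  (gR * I / (1 + gR * I))^i
}

#' Early-extinction probability of a mutant arising during treatment
#'
#' Same branching-process calculation for a single resistant mutant
#' appearing at time `t0` after drug addition: the exponent restarts at
#' `t0` (`eta(t) = rho(t) - rho(t0)`), and the lineage dies with
#' probability `gR I(t0) / (1 + gR I(t0))`,
#' `I(t0) = integral_{t0}^Inf e^{eta(u)} du`. At `t0 = 0` this equals
#' [p_extinct_lineage()] with `i = 1`; as `t0 -> Inf` it tends to the
#' bare ratio `gR/fR`.
#'
#' @param t0 Appearance time(s), `>= 0` (vectorized).
#' @inheritParams p_extinct_lineage
#' @return Extinction probability/ies.
#' @export
p_extinct_lineage_after <- function(t0, decay, fR, gR) {
  stopifnot(all(t0 >= 0))
  if (fR <= gR) return(rep(1, length(t0)))
  vapply(t0, function(tt) {
    I <- .survival_integral(decay, fR, gR, t0 = tt)
    gR * I / (1 + gR * I)
  }, numeric(1))
}

#' Appearance-time-averaged extinction probability of de-novo mutants
#'
#' Mutants appear during the kill phase at a rate proportional to the
#' division flux `S(t)(1 - S(t)/K)`; normalizing gives the appearance
#' density, and averaging [p_extinct_lineage_after()] over it yields
#' `pRe'`, the probability that the (assumed single) drug-phase mutant
#' lineage dies out.
#'
#' @param decay A [deterministic_decay()].
#' @param params A [model_params()] (supplies `fR`, `gR`).
#' @return `pRe'` in `(0, 1]`.
#' @export
p_extinct_denovo_avg <- function(decay, params) {
  fR <- params$rates_drug$fitness[["R"]]
  gR <- params$rates_drug$death[["R"]]
  if (fR <= gR) return(1)
  if (decay$S0 == 0) {
    warning("degenerate appearance density (S = 0); returning gR/fR")
    return(gR / fR)
  }
  upper <- .decay_horizon(decay, level = 1e-9)
  w <- function(tt) {
    s <- s_of_t(decay, tt)
    s * pmax(0, 1 - s / decay$K)
  }
  Z <- stats::integrate(w, 0, upper, rel.tol = 1e-8,
                        subdivisions = 1000L)$value
  num <- stats::integrate(function(tt) {
    p_extinct_lineage_after(tt, decay, fR, gR) * w(tt)
  }, 0, upper, rel.tol = 1e-6, subdivisions = 1000L)$value
  num / Z
}

# shared first factor of Eqs for p0: 1 - pR * sum_i pRc(i) (1 - pRe(i))
.p0_first_factor <- function(params, decay) {
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  fR <- params$rates_no_drug$fitness[["R"]]
  gR <- params$rates_no_drug$death[["R"]]
  if (params$K * params$mu1 > 0.1)
    warning("K*mu1 = ", params$K * params$mu1,
            " > 0.1: outside the rare-mutation regime")
  N <- as.integer(.round_half_up(equilibrium_size(fS, gS, params$K)))
  stats <- lineage_stats(moran_spec(N, fS, gS, fR, gR),
                         conditioning = "extinction")
  pR <- p_preexisting(N, params$mu1, gS, stats)
  fR_drug <- params$rates_drug$fitness[["R"]]
  gR_drug <- params$rates_drug$death[["R"]]
  p1 <- p_extinct_lineage(1, decay, fR_drug, gR_drug)
  i <- seq_len(N - 1)
  rescue_sum <- sum(stats$pRc * (1 - p1^i))
  list(first_factor = 1 - pR * rescue_sum, pR = pR, pRc = stats$pRc,
       p1 = p1, N = N)
}

#' Eradication probability, perfect biostatic drug
#'
#' Assembles `p0 = 1 - pR sum_{i=1}^{N-1} pRc(i) (1 - pRe(i))`: the
#' population survives the first drug addition only if a resistant
#' lineage preexists (probability `pR`), had `i` copies (probability
#' `pRc(i)`), and escapes early extinction (probability `1 - pRe(i)`).
#' Valid when the drug phase is long enough to kill a resistance-free
#' population (`T/2 >> tauS`) and mutations are rare (`K mu1 << 1`);
#' requires a perfect biostatic drug (`f'S = 0`), under which no mutant
#' can arise during the drug phase.
#'
#' @param params A [model_params()] with `fS_drug = 0`.
#' @return A list of class `rescue_prediction` with `p0` and all
#'   intermediate quantities (`pR`, `pRc`, `pRe1`, `N`, ...).
#' @export
p0_eq1 <- function(params) {
  if (params$rates_drug$fitness[["S"]] != 0)
    stop("p0_eq1 requires a perfect biostatic drug (fS_drug = 0); ",
         "use p0_eq4 for the general case")
  decay <- decay_from_params(params)
  ff <- .p0_first_factor(params, decay)
  structure(list(p0 = ff$first_factor, pR = ff$pR, pRc = ff$pRc,
                 pRe1 = ff$p1, N = ff$N, pRa = 0, pRe_denovo = NA_real_,
                 mode = "perfect_biostatic"),
            class = "rescue_prediction")
}

#' Eradication probability, general above-MIC drug
#'
#' The general assembly
#' `p0 = [1 - pR sum_i pRc(i)(1 - pRe(i))] * [1 - pRa (1 - pRe')]`:
#' the first factor is rescue by preexisting mutants (as in the perfect
#' biostatic case but with the drug-dependent decay in `pRe`); the second
#' is rescue by a mutant arising during the kill phase, which happens
#' with probability `pRa = N_div mu1` ([n_div()]) and survives with
#' probability `1 - pRe'` ([p_extinct_denovo_avg()]). For `f'S = 0` the
#' second factor is 1 and the result coincides with [p0_eq1()].
#'
#' @param params A [model_params()] with `gS_drug > fS_drug` (above MIC).
#' @return A list of class `rescue_prediction`.
#' @export
p0_eq4 <- function(params) {
  fp <- params$rates_drug$fitness[["S"]]
  gp <- params$rates_drug$death[["S"]]
  if (gp <= fp) stop("p0_eq4 requires an above-MIC drug (gS_drug > fS_drug)")
  decay <- decay_from_params(params)
  ff <- .p0_first_factor(params, decay)
  if (fp == 0) {
    pRa <- 0
    pRe_dn <- NA_real_
    second <- 1
  } else {
    N0 <- .round_half_up(decay$S0)
    tauS <- tau_birth_death_logistic(fp, gp, params$K, N0)
    pRa <- n_div(params, tauS, decay) * params$mu1
    if (pRa > 0.1)
      warning("Ndiv*mu1 = ", signif(pRa, 3),
              " > 0.1: de-novo appearance not rare")
    pRe_dn <- p_extinct_denovo_avg(decay, params)
    second <- 1 - pRa * (1 - pRe_dn)
  }
  structure(list(p0 = ff$first_factor * second, pR = ff$pR, pRc = ff$pRc,
                 pRe1 = ff$p1, N = ff$N, pRa = pRa, pRe_denovo = pRe_dn,
                 mode = if (fp == 0) "perfect_biostatic" else "general"),
            class = "rescue_prediction")
}

#' @export
print.rescue_prediction <- function(x, ...) {
  cat("p0 =", signif(x$p0, 5), "(", x$mode, ")\n")
  cat("  pR =", signif(x$pR, 4), " pRe(1) =", signif(x$pRe1, 4),
      " N =", x$N, "\n")
  if (x$pRa > 0)
    cat("  pRa =", signif(x$pRa, 4), " pRe' =", signif(x$pRe_denovo, 4), "\n")
  invisible(x)
}
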