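#' Per-environment division and death rates
#'
#' Bundles the maximal division rates (fitnesses) and death rates of the
#' three genotypes — sensitive (S), resistant (R) and resistant-compensated
#' (C) — in one environment (with or without drug). The drug only acts on
#' S: R and C keep the same rates in both environments, which
#' [model_params()] enforces.
#'
#' @param fS,fR,fC Maximal division rates (per unit time) of S, R, C.
#' @param gS,gR,gC Death rates (per unit time) of S, R, C.
#' @return An object of class `env_rates`: a list with numeric vectors
#'   `fitness` and `death`, each named `c("S", "R", "C")`.
#' @export
env_rates <- function(fS, fR, fC, gS, gR, gC) {
  fitness <- c(S = fS, R = fR, C = fC)
  death <- c(S = gS, R = gR, C = gC)
  if (any(!is.finite(c(fitness, death))) || any(c(fitness, death) < 0))
    stop("all rates must be finite and >= 0")
  structure(list(fitness = fitness, death = death), class = "env_rates")
}

#' Full parameter set of the three-genotype model
#'
#' The model has three genotypes on the mutation path S -> R -> C (no back
#' mutation): sensitive, resistant (cost delta = fS - fR), and
#' resistant-compensated. Division rates are logistic, `f * (1 - N/K)`;
#' mutations happen in one daughter at division (S daughters are R with
#' probability `mu1`, R daughters are C with probability `mu2`). The drug
#' changes only the S rates (`fS_drug`, `gS_drug`).
#'
#' Defaults are the baseline parameter choice used throughout:
#' `fS = 1` (which sets the time unit, so one unit is a generation of S
#' without drug at low density), `fR = 0.9`, `fC = 1`,
#' `gS = gR = gC = 0.1`, `mu1 = 1e-5`, `mu2 = 1e-3`.
#'
#' @param K Carrying capacity (individuals), `>= 1`.
#' @param fS,fR,fC Division rates without drug.
#' @param gS,gR,gC Death rates without drug.
#' @param fS_drug,gS_drug S division/death rates with drug (a perfect
#'   biostatic has `fS_drug = 0`; a pure biocidal has `fS_drug = fS`,
#'   `gS_drug > gS`).
#' @param mu1 Mutation probability S -> R per division, in `[0, 1]`.
#' @param mu2 Mutation probability R -> C per division, in `[0, 1]`.
#' @return An object of class `model_params` with elements `rates_no_drug`
#'   and `rates_drug` (both [env_rates()]), `K`, `mu1`, `mu2`.
#' @examples
#' p <- model_params(K = 1000)
#' p$rates_drug$death[["S"]]
#' @export
model_params <- function(K, fS = 1, fR = 0.9, fC = 1,
                         gS = 0.1, gR = 0.1, gC = 0.1,
                         fS_drug = 0, gS_drug = gS,
                         mu1 = 1e-5, mu2 = 1e-3) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1)
  if (mu1 < 0 || mu1 > 1 || mu2 < 0 || mu2 > 1)
    stop("mu1 and mu2 must lie in [0, 1]")
  if (fS != 1)
    warning("convention: fS = 1 sets the time unit; fS = ", fS,
            " is allowed but rescales time")
  structure(list(
    rates_no_drug = env_rates(fS, fR, fC, gS, gR, gC),
    rates_drug = env_rates(fS_drug, fR, fC, gS_drug, gR, gC),
    K = as.numeric(K), mu1 = mu1, mu2 = mu2
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Three-genotype model (S -> R -> C), K =", x$K, "\n")
  cat("  no drug : f =", paste(x$rates_no_drug$fitness, collapse = "/"),
      " g =", paste(x$rates_no_drug$death, collapse = "/"), "\n")
  cat("  drug    : f =", paste(x$rates_drug$fitness, collapse = "/"),
      " g =", paste(x$rates_drug$death, collapse = "/"), "\n")
  cat("  mu1 =", x$mu1, " mu2 =", x$mu2, "\n")
  invisible(x)
}

#' Periodic antimicrobial schedule
#'
#' The environment alternates with period `T`: drug absent on
#' `[kT, kT + T/2)` and present on `[kT + T/2, (k+1)T)` for integer k, so
#' the first drug addition happens at `T/2`. Constant environments are
#' available via `mode`.
#'
#' @param period Alternation period `T > 0` (ignored for constant modes).
#' @param mode One of `"periodic"`, `"always_off"`, `"always_on"`.
#' @return An object of class `alternation_schedule`.
#' @export
alternation_schedule <- function(period = NULL,
                                 mode = c("periodic", "always_off", "always_on")) {
  mode <- match.arg(mode)
  if (mode == "periodic") {
    stopifnot(is.numeric(period), length(period) == 1, period > 0)
  } else {
    period <- NA_real_
  }
  structure(list(period = period, mode = mode), class = "alternation_schedule")
}

#' Query the environment at a time point
#'
#' @param schedule An [alternation_schedule()].
#' @param t Time, `>= 0`.
#' @return A list with `drug_on` (logical), `rates` (`"drug"` or
#'   `"no_drug"`, the element of [model_params()] in force), and
#'   `next_switch` (time of the next environment change, `Inf` for
#'   constant modes).
#' @examples
#' environment_at(alternation_schedule(20), 10)
#' @export
environment_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "alternation_schedule"),
            is.numeric(t), length(t) == 1)
  if (t < 0) stop("t must be >= 0")
  if (schedule$mode != "periodic") {
    on <- schedule$mode == "always_on"
    return(list(drug_on = on, rates = if (on) "drug" else "no_drug",
                next_switch = Inf))
  }
  Tp <- schedule$period
  k <- floor(t / Tp)
  phase <- t - k * Tp
  on <- phase >= Tp / 2
  list(drug_on = on,
       rates = if (on) "drug" else "no_drug",
       next_switch = if (on) (k + 1) * Tp else k * Tp + Tp / 2)
}

#' Drug-strength ratio R
#'
#' `R = (g'S - f'S) / g'S` is a non-dimensional measure of drug strength:
#' zero exactly at the minimum inhibitory concentration (MIC, where the
#' drug-exposed death and division rates of S balance), positive above the
#' MIC, negative below. A perfect biostatic (`f'S = 0`) has `R = 1`.
#'
#' @param f_prime S division rate with drug.
#' @param g_prime S death rate with drug, `> 0`.
#' @return The ratio, a single number `<= 1`.
#' @export
r_ratio <- function(f_prime, g_prime) {
  if (!is.numeric(g_prime) || any(g_prime <= 0))
    stop("g_prime must be > 0")
  (g_prime - f_prime) / g_prime
}

#' Invert the drug-strength ratio into rates
#'
#' Fixed conventions for mapping a target ratio `R` back onto drug-phase
#' rates: a biostatic drug keeps `g'S = gS` and sets `f'S = gS * (1 - R)`;
#' a biocidal drug keeps `f'S = fS` and sets `g'S = fS / (1 - R)`.
#'
#' @param R Target drug-strength ratio, `< 1` for biocidal.
#' @param params A [model_params()] providing the no-drug `fS`, `gS`.
#' @param mode `"biostatic"` or `"biocidal"`.
#' @return A [model_params()] with the drug-phase S rates replaced.
#' @export
params_at_ratio <- function(R, params, mode = c("biostatic", "biocidal")) {
  mode <- match.arg(mode)
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  if (mode == "biostatic") {
    fp <- gS * (1 - R); gp <- gS
    if (fp < 0) stop("biostatic parameterization needs R <= 1")
  } else {
    if (R >= 1) stop("biocidal parameterization needs R < 1")
    fp <- fS; gp <- fS / (1 - R)
  }
  out <- params
  out$rates_drug <- env_rates(fp,
                              params$rates_drug$fitness[["R"]],
                              params$rates_drug$fitness[["C"]],
                              gp,
                              params$rates_drug$death[["R"]],
                              params$rates_drug$death[["C"]])
  out
}

#' Classify the dynamical regime of a parameter set
#'
#' Reports the quantities that organize the phase diagram: the
#' drug-strength ratio `R`; the fast-alternation effective rates
#' `f~S = (fS + f'S)/2` and `g~S = (gS + g'S)/2`; whether the drug phase
#' is above the MIC (`g'S > f'S`); whether infinitely fast alternations
#' drive net decay (`f~S < g~S`, equivalent to `g'S > 2 fS - gS` for a
#' pure biocidal); and the critical ratio `(fS - gS)/(2 fS - gS)` above
#' which a pure biocidal kills even at short periods.
#'
#' @param params A [model_params()].
#' @param schedule Optional [alternation_schedule()], echoed in the report.
#' @return A list of class `regime_report`.
#' @export
classify_regime <- function(params, schedule = NULL) {
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  fp <- params$rates_drug$fitness[["S"]]
  gp <- params$rates_drug$death[["S"]]
  f_eff <- (fS + fp) / 2
  g_eff <- (gS + gp) / 2
  structure(list(
    R_ratio = r_ratio(fp, gp),
    f_eff = f_eff, g_eff = g_eff,
    above_MIC = gp > fp,
    fast_alternation_decay = f_eff < g_eff,
    critical_ratio_biocidal = (fS - gS) / (2 * fS - gS),
    period = if (!is.null(schedule)) schedule$period else NA_real_
  ), class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("R =", signif(x$R_ratio, 4),
      "| f~S =", x$f_eff, " g~S =", x$g_eff, "\n")
  cat("above MIC:", x$above_MIC,
      "| fast-alternation decay:", x$fast_alternation_decay, "\n")
  cat("biocidal short-period kill threshold R* =",
      signif(x$critical_ratio_biocidal, 4), "\n")
  invisible(x)
}

.config_keys <- c("fS", "fS_drug", "fR", "fC", "gS", "gS_drug", "gR", "gC",
                  "K", "mu1", "mu2", "T", "init_S", "init_R", "init_C",
                  "t_max", "n_rep", "seed")

#' Read a JSON configuration file
#'
#' Keys: `fS, fS_drug, fR, fC, gS, gS_drug, gR, gC, K, mu1, mu2, T,
#' init_S, init_R, init_C, t_max, n_rep, seed`. Unknown keys are a hard
#' error; absent keys fall back to the package defaults (see
#' [model_params()]; `init_S = 10`, `init_R = init_C = 0`,
#' `t_max = 1e6`, `n_rep = 1000`).
#'
#' @param path Path to a JSON file.
#' @return A list with `params` ([model_params()]), `schedule`
#'   ([alternation_schedule()] or `NULL` if `T` absent), `init` (named
#'   integer vector), `t_max`, `n_rep`, `seed`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  get <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  gS <- get("gS", 0.1)
  params <- model_params(
    K = get("K", 1000),
    fS = get("fS", 1), fR = get("fR", 0.9), fC = get("fC", 1),
    gS = gS, gR = get("gR", 0.1), gC = get("gC", 0.1),
    fS_drug = get("fS_drug", 0), gS_drug = get("gS_drug", gS),
    mu1 = get("mu1", 1e-5), mu2 = get("mu2", 1e-3))
  schedule <- if (!is.null(raw[["T"]])) alternation_schedule(raw[["T"]]) else NULL
  list(params = params,
       schedule = schedule,
       init = c(S = get("init_S", 10), R = get("init_R", 0), C = get("init_C", 0)),
       t_max = get("t_max", 1e6),
       n_rep = get("n_rep", 1000),
       seed = get("seed", NULL))
}
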