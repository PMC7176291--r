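.outcome_labels <- c("EXTINCT", "C_FIXED", "TIMEOUT")

#' Simulation configuration
#'
#' @param params A [model_params()].
#' @param schedule An [alternation_schedule()].
#' @param init Named vector of initial counts; the default, 10 sensitive
#'   cells, models the bottleneck at the start of an infection.
#' @param t_max Time safeguard (simulations that neither go extinct nor
#'   fix C by `t_max` return a `TIMEOUT` outcome).
#' @param record One of `"absorption"` (outcome only), `"full"` (every
#'   event), or `"sampled"` (state at a regular grid).
#' @param sample_dt Grid spacing for `record = "sampled"`.
#' @param max_records Cap on stored records (simulation continues past the
#'   cap; the trajectory is flagged truncated).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, schedule, init = c(S = 10, R = 0, C = 0),
                       t_max = 1e6,
                       record = c("absorption", "full", "sampled"),
                       sample_dt = 1, max_records = 5e6) {
  record <- match.arg(record)
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "alternation_schedule"),
            t_max > 0, all(init >= 0))
  init <- init[c("S", "R", "C")]
  if (anyNA(init)) stop("init must name S, R and C counts")
  structure(list(params = params, schedule = schedule, init = init,
                 t_max = t_max, record = record, sample_dt = sample_dt,
                 max_records = max_records),
            class = "sim_config")
}

.run_cpp <- function(config) {
  p <- config$params
  sched_mode <- match(config$schedule$mode,
                      c("periodic", "always_off", "always_on")) - 1L
  record_mode <- match(config$record, c("absorption", "full", "sampled")) - 1L
  .gillespie_run_cpp(
    p$rates_no_drug$fitness, p$rates_no_drug$death,
    p$rates_drug$fitness, p$rates_drug$death,
    p$K, p$mu1, p$mu2,
    if (is.na(config$schedule$period)) 1 else config$schedule$period,
    sched_mode,
    config$init[["S"]], config$init[["R"]], config$init[["C"]],
    config$t_max, record_mode, config$sample_dt,
    as.integer(config$max_records))
}

#' Run one exact stochastic realization
#'
#' Gillespie simulation of the full process: every individual division,
#' mutation and death event is drawn with its exact rate. Waiting times
#' are exponential in the total propensity; when a drawn event would cross
#' the next environment switch, the clock advances to the switch and the
#' waiting time is re-drawn under the new rates (exact, because
#' propensities are piecewise-constant in time given the state). At an S
#' division the single daughter is R with probability `mu1` (the parent
#' is never altered); at an R division the daughter is C with probability
#' `mu2`. Absorbing stops: extinction (`N = 0`) and C fixation
#' (`S = 0, R = 0, C > 0`).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer; if given, `set.seed(seed)` is called
#'   first so the run is reproducible.
#' @return A list of class `sim_outcome`: `kind` (`"EXTINCT"`,
#'   `"C_FIXED"` or `"TIMEOUT"`), `t_event`, final counts, `n_events`,
#'   and (unless `record = "absorption"`) `traj`, a data.frame with
#'   columns `t, S, R, C, drug_on`.
#' @examples
#' cfg <- sim_config(model_params(K = 100), alternation_schedule(20),
#'                   t_max = 500)
#' run_trajectory(cfg, seed = 1)$kind
#' @export
run_trajectory <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- .run_cpp(config)
  out <- list(kind = .outcome_labels[res$kind + 1L],
              t_event = res$t_event,
              t_end = res$t_end,
              final = c(S = res$S, R = res$R, C = res$C),
              n_events = res$n_events,
              truncated = res$truncated)
  if (!is.null(res$traj)) out$traj <- res$traj
  class(out) <- "sim_outcome"
  out
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat("outcome:", x$kind,
      if (!is.na(x$t_event)) paste0("at t = ", signif(x$t_event, 6)) else "",
      "\nfinal counts: S =", x$final[["S"]], " R =", x$final[["R"]],
      " C =", x$final[["C"]], " (", x$n_events, "events )\n")
  invisible(x)
}

.spawn_seeds <- function(n_rep, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_rep, replace = FALSE)
}

.wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, centre - hw), hi = min(1, centre + hw))
}

#' Monte-Carlo estimate of the eradication probability p0
#'
#' Runs `n_rep` independent replicates of [run_trajectory()] (each on its
#' own sub-seed spawned from `seed`) and estimates the probability `p0`
#' that the population goes extinct before compensated resistance (C)
#' fixes. `TIMEOUT` replicates are excluded with a warning and reported
#' separately.
#'
#' @param config A [sim_config()] (its `record` is forced to
#'   `"absorption"`).
#' @param n_rep Number of replicates, `>= 1`.
#' @param seed Master seed for the replicate seed stream.
#' @return A list of class `p0_estimate`: `p0`, `ci` (95% Wilson),
#'   `n_rep`, `counts` (per outcome kind), `mean_t_ext`, `mean_t_fix`,
#'   `seeds`.
#' @export
estimate_p0 <- function(config, n_rep, seed = NULL) {
  stopifnot(n_rep >= 1)
  config$record <- "absorption"
  seeds <- .spawn_seeds(n_rep, seed)
  kinds <- character(n_rep)
  t_event <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    r <- run_trajectory(config, seed = seeds[i])
    kinds[i] <- r$kind
    t_event[i] <- if (is.na(r$t_event)) NA_real_ else r$t_event
  }
  counts <- table(factor(kinds, levels = .outcome_labels))
  n_used <- n_rep - counts[["TIMEOUT"]]
  if (n_used == 0) stop("all replicates timed out; increase t_max")
  if (counts[["TIMEOUT"]] > 0)
    warning(counts[["TIMEOUT"]], " replicate(s) timed out and were excluded")
  k <- counts[["EXTINCT"]]
  structure(list(
    p0 = k / n_used,
    ci = .wilson_ci(k, n_used),
    n_rep = n_used,
    counts = counts,
    mean_t_ext = if (k > 0) mean(t_event[kinds == "EXTINCT"]) else NA_real_,
    mean_t_fix = if (counts[["C_FIXED"]] > 0)
      mean(t_event[kinds == "C_FIXED"]) else NA_real_,
    seeds = seeds
  ), class = "p0_estimate")
}

#' @export
print.p0_estimate <- function(x, ...) {
  cat(sprintf("p0 = %.4g  (95%% CI %.4g-%.4g, n = %d)\n",
              x$p0, x$ci[["lo"]], x$ci[["hi"]], x$n_rep))
  cat("outcomes:", paste(names(x$counts), as.integer(x$counts),
                         sep = "=", collapse = "  "), "\n")
  cat("mean t_ext =", signif(x$mean_t_ext, 5),
      " mean t_fix =", signif(x$mean_t_fix, 5), "\n")
  invisible(x)
}

#' Probability that extinction beats a half-period of drug
#'
#' Simulates a pure-sensitive population (`mu1 = 0`) with drug
#' continuously applied, starting from the drug-free equilibrium size
#' `N0 = round(K (1 - gS/fS))`, and returns the fraction of replicates
#' whose extinction time is below `T/2`. When this fraction `p` is
#' appreciable even though the mean extinction time exceeds `T/2`, the
#' population typically dies after about `1/p` periods — the stochastic
#' multi-period extinction route.
#'
#' @param params A [model_params()] (drug-phase rates are used).
#' @param period Alternation period `T`.
#' @param n_rep Replicates.
#' @param seed Master seed.
#' @return A list of class `p0_estimate` whose `p0` slot holds `p`.
#' @export
estimate_half_period_extinction_prob <- function(params, period, n_rep,
                                                 seed = NULL) {
  stopifnot(n_rep >= 1, period > 0)
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  N0 <- .round_half_up(params$K * (1 - gS / fS))
  p <- params
  p$mu1 <- 0; p$mu2 <- 0
  # t_max = T/2: replicates not extinct by then time out, i.e. count as
  # "not within a half-period" (the contracted behaviour)
  cfg <- sim_config(p, alternation_schedule(mode = "always_on"),
                    init = c(S = N0, R = 0, C = 0), t_max = period / 2)
  seeds <- .spawn_seeds(n_rep, seed)
  k <- 0L
  t_ext <- numeric(0)
  for (i in seq_len(n_rep)) {
    r <- run_trajectory(cfg, seed = seeds[i])
    if (r$kind == "EXTINCT") { k <- k + 1L; t_ext <- c(t_ext, r$t_event) }
  }
  structure(list(
    p0 = k / n_rep,
    ci = .wilson_ci(k, n_rep),
    n_rep = n_rep,
    counts = c(EXTINCT = k, C_FIXED = 0L, TIMEOUT = n_rep - k),
    mean_t_ext = if (k > 0) mean(t_ext) else NA_real_,
    mean_t_fix = NA_real_,
    seeds = seeds
  ), class = "p0_estimate")
}

#' Stochastic single-lineage survival oracle
#'
#' Simulates `n_rep` independent resistant lineages (one founder each)
#' with death rate `gR` per head and division rate `fR (1 - S(t)/K)` per
#' head on top of a deterministic sensitive background `S(t)` (a
#' [deterministic_decay()]), by exact thinning. Used as the independent
#' check of the branching-process extinction probability
#' [p_extinct_lineage()].
#'
#' @param n_rep Number of lineages.
#' @param decay A [deterministic_decay()].
#' @param fR,gR Resistant division and death rates.
#' @param t0 Lineage start time (default 0 = the moment of drug addition).
#' @param n_cap Lineage size counted as established/survived.
#' @param t_safeguard Hard time cap per lineage.
#' @param seed Optional seed.
#' @return Fraction of lineages that went extinct.
#' @export
sim_lineage_extinction_fraction <- function(n_rep, decay, fR, gR, t0 = 0,
                                            n_cap = 200, t_safeguard = 1e5,
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(decay, "deterministic_decay"))
  type <- if (decay$f_prime == 0) 0L else 1L
  k <- .sim_r_lineages_cpp(as.integer(n_rep), fR, gR, type,
                           decay$S0, decay$K, decay$f_prime, decay$g_prime,
                           t0, as.integer(n_cap), t_safeguard)
  k / n_rep
}
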