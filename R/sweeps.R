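# Sweep drivers reproducing the figure-level experiments: p0 versus
# alternation period, p0 versus carrying capacity, and the period-by-
# drug-strength phase diagram with its predicted transition lines.
# CSV is the contract; every row is reproducible from the JSON metadata
# sidecar (config + per-cell seed).

# model_params as plain nested lists, for JSON metadata sidecars
.params_plain <- function(p) {
  flat <- function(r) list(fitness = as.list(r$fitness),
                           death = as.list(r$death))
  list(rates_no_drug = flat(p$rates_no_drug), rates_drug = flat(p$rates_drug),
       K = p$K, mu1 = p$mu1, mu2 = p$mu2)
}

.write_sidecar <- function(path, meta) {
  if (is.null(path)) return(invisible(NULL))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.analytic_p0 <- function(params, period) {
  # analytic formulas hold in the large-period window tauS << T/2 << tauV;
  # rule used: T/2 >= 2 tauS and T/2 <= tauV / 10
  fp <- params$rates_drug$fitness[["S"]]
  gp <- params$rates_drug$death[["S"]]
  if (gp <= fp) return(NA_real_)
  tauS <- solve_T_threshold(params) / 2
  tauV <- valley_crossing_time(params)
  if (period / 2 < 2 * tauS || period / 2 > tauV / 10) return(NA_real_)
  if (fp == 0) p0_eq1(params)$p0 else p0_eq4(params)$p0
}

#' Sweep the eradication probability over the alternation period
#'
#' One Monte-Carlo cell per period in `periods`; the analytic column is
#' filled from [p0_eq1()]/[p0_eq4()] for cells in the large-period window
#' (`tauS << T/2 << tauV`) and left `NA` elsewhere.
#'
#' @param params A [model_params()].
#' @param periods Numeric vector of alternation periods (non-empty).
#' @param n_rep Replicates per cell.
#' @param seed Master seed (one sub-seed per cell).
#' @param init Initial counts.
#' @param t_max Per-run time safeguard.
#' @param csv Optional output path; a `.meta.json` sidecar is written
#'   next to it.
#' @return A data.frame with columns `T, K, p0, ci_lo, ci_hi, n_rep,
#'   n_timeout, mean_t_ext, mean_t_fix, p0_analytic, seed`.
#' @export
sweep_p0_vs_T <- function(params, periods, n_rep = 1000, seed = NULL,
                          init = c(S = 10, R = 0, C = 0), t_max = 1e6,
                          csv = NULL) {
  if (length(periods) == 0) stop("empty period grid")
  seeds <- .spawn_seeds(length(periods), seed)
  rows <- vector("list", length(periods))
  for (k in seq_along(periods)) {
    est <- tryCatch(
      estimate_p0(sim_config(params, alternation_schedule(periods[k]),
                             init = init, t_max = t_max),
                  n_rep, seed = seeds[k]),
      error = function(e) e)
    if (inherits(est, "error")) {
      warning("cell T = ", periods[k], " failed: ", conditionMessage(est))
      rows[[k]] <- data.frame(T = periods[k], K = params$K, p0 = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              n_rep = 0L, n_timeout = NA_integer_,
                              mean_t_ext = NA_real_, mean_t_fix = NA_real_,
                              p0_analytic = NA_real_, seed = seeds[k])
      next
    }
    rows[[k]] <- data.frame(
      T = periods[k], K = params$K, p0 = est$p0,
      ci_lo = est$ci[["lo"]], ci_hi = est$ci[["hi"]], n_rep = est$n_rep,
      n_timeout = as.integer(est$counts[["TIMEOUT"]]),
      mean_t_ext = est$mean_t_ext, mean_t_fix = est$mean_t_fix,
      p0_analytic = .analytic_p0(params, periods[k]), seed = seeds[k])
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) {
    utils::write.csv(out, csv, row.names = FALSE)
    .write_sidecar(csv, list(kind = "p0_vs_T", params = .params_plain(params),
                             periods = periods, n_rep = n_rep,
                             master_seed = seed, cell_seeds = seeds,
                             init = as.list(init), t_max = t_max,
                             version = as.character(utils::packageVersion("amrcycle"))))
  }
  out
}

#' Sweep the eradication probability over carrying capacity
#'
#' @param K_grid Carrying capacities (non-empty).
#' @param period Alternation period (should sit in the large-period
#'   window for the analytic column to be meaningful).
#' @inheritParams sweep_p0_vs_T
#' @return A data.frame, one row per K.
#' @export
sweep_p0_vs_K <- function(params, K_grid, period, n_rep = 1000, seed = NULL,
                          init = c(S = 10, R = 0, C = 0), t_max = 1e6,
                          csv = NULL) {
  if (length(K_grid) == 0) stop("empty K grid")
  seeds <- .spawn_seeds(length(K_grid), seed)
  rows <- vector("list", length(K_grid))
  for (k in seq_along(K_grid)) {
    p <- params
    p$K <- K_grid[k]
    est <- estimate_p0(sim_config(p, alternation_schedule(period),
                                  init = init, t_max = t_max),
                       n_rep, seed = seeds[k])
    rows[[k]] <- data.frame(
      K = K_grid[k], T = period, p0 = est$p0,
      ci_lo = est$ci[["lo"]], ci_hi = est$ci[["hi"]], n_rep = est$n_rep,
      n_timeout = as.integer(est$counts[["TIMEOUT"]]),
      mean_t_ext = est$mean_t_ext, mean_t_fix = est$mean_t_fix,
      p0_analytic = .analytic_p0(p, period), seed = seeds[k])
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) {
    utils::write.csv(out, csv, row.names = FALSE)
    .write_sidecar(csv, list(kind = "p0_vs_K", params = .params_plain(params),
                             K_grid = K_grid, period = period, n_rep = n_rep,
                             master_seed = seed, cell_seeds = seeds,
                             init = as.list(init), t_max = t_max,
                             version = as.character(utils::packageVersion("amrcycle"))))
  }
  out
}

#' Predicted transition lines of the period-by-strength phase diagram
#'
#' For each drug-strength ratio in `R_grid`, reports the three predicted
#' boundaries of the extinction region: the single-phase-kill line
#' `T/2 = tauS(R)`; the race line `tRa = tauS` (the sub-MIC ratio below
#' which resistance fixes before stochastic extinction — a single value,
#' independent of `T`); and, for biocidal drugs, the fast-alternation
#' kill threshold `R = (fS - gS)/(2 fS - gS)`.
#'
#' @param params A [model_params()].
#' @param R_grid Drug-strength ratios (`< 1`).
#' @param mode `"biostatic"` or `"biocidal"` (rate parameterization, see
#'   [params_at_ratio()]).
#' @return A data.frame with columns `R, T_half_eq_tauS` (the period
#'   `2 tauS(R)`), plus attributes `R_race` (root of `tRa = tauS`, `NA`
#'   if absent from the bracket) and `R_fast_kill`.
#' @export
transition_lines <- function(params, R_grid, mode = c("biostatic", "biocidal")) {
  mode <- match.arg(mode)
  fS <- params$rates_no_drug$fitness[["S"]]
  gS <- params$rates_no_drug$death[["S"]]
  gR <- params$rates_no_drug$death[["R"]]
  fR <- params$rates_no_drug$fitness[["R"]]
  N0 <- .round_half_up(equilibrium_size(fS, gS, params$K))
  tau_at <- function(R) {
    pr <- params_at_ratio(R, params, mode)
    tau_birth_death_logistic(pr$rates_drug$fitness[["S"]],
                             pr$rates_drug$death[["S"]], params$K, N0)
  }
  tRa_at <- function(R) {
    # only defined sub-MIC (R < 0): needs the with-drug equilibrium N'
    pr <- params_at_ratio(R, params, mode)
    fp <- pr$rates_drug$fitness[["S"]]
    gp <- pr$rates_drug$death[["S"]]
    if (fp <= gp) return(Inf)
    Np <- .round_half_up(equilibrium_size(fp, gp, params$K))
    if (Np < 2) return(Inf)
    pfix <- fixation_probability(moran_spec(Np, fp, gp, fR, gR))
    appearance_fixation_time(Np, params$mu1, gp, pfix)
  }
  lines <- data.frame(R = R_grid,
                      T_half_eq_tauS = 2 * vapply(R_grid, tau_at, numeric(1)))
  # race line: tRa(R) = tauS(R), bracketed strictly below the MIC
  g <- function(R) log(tRa_at(R)) - log(tau_at(R))
  lo <- -0.9; hi <- -1e-4
  R_race <- NA_real_
  if (is.finite(g(lo)) && is.finite(g(hi)) && sign(g(lo)) != sign(g(hi))) {
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    }
    R_race <- (lo + hi) / 2
  }
  attr(lines, "R_race") <- R_race
  attr(lines, "R_fast_kill") <-
    if (mode == "biocidal") (fS - gS) / (2 * fS - gS) else NA_real_
  lines
}

#' Simulated phase diagram over period and drug strength
#'
#' Monte-Carlo grid of the eradication probability over alternation
#' period and drug-strength ratio, with the predicted transition lines
#' attached for overlay. Biostatic mode varies `f'S` at `g'S = gS`;
#' biocidal mode varies `g'S` at `f'S = fS`.
#'
#' @param params A [model_params()].
#' @param periods Period grid.
#' @param R_grid Drug-strength grid.
#' @param mode `"biostatic"` or `"biocidal"`.
#' @inheritParams sweep_p0_vs_T
#' @return A data.frame in long format (`T, R, p0, ci_lo, ci_hi, n_rep,
#'   seed`) with the [transition_lines()] result in attribute `lines`.
#' @export
heatmap_T_R <- function(params, periods, R_grid,
                        mode = c("biostatic", "biocidal"),
                        n_rep = 1000, seed = NULL,
                        init = c(S = 10, R = 0, C = 0), t_max = 1e6,
                        csv = NULL) {
  mode <- match.arg(mode)
  if (length(periods) == 0 || length(R_grid) == 0) stop("empty grid")
  grid <- expand.grid(T = periods, R = R_grid)
  seeds <- .spawn_seeds(nrow(grid), seed)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    p <- params_at_ratio(grid$R[k], params, mode)
    est <- estimate_p0(sim_config(p, alternation_schedule(grid$T[k]),
                                  init = init, t_max = t_max),
                       n_rep, seed = seeds[k])
    rows[[k]] <- data.frame(T = grid$T[k], R = grid$R[k], p0 = est$p0,
                            ci_lo = est$ci[["lo"]], ci_hi = est$ci[["hi"]],
                            n_rep = est$n_rep, seed = seeds[k])
  }
  out <- do.call(rbind, rows)
  attr(out, "lines") <- transition_lines(params, R_grid, mode)
  if (!is.null(csv)) {
    utils::write.csv(out, csv, row.names = FALSE)
    .write_sidecar(csv, list(kind = "heatmap_T_R", mode = mode,
                             params = .params_plain(params), periods = periods,
                             R_grid = R_grid, n_rep = n_rep,
                             master_seed = seed, cell_seeds = seeds,
                             init = as.list(init), t_max = t_max,
                             version = as.character(utils::packageVersion("amrcycle"))))
  }
  out
}
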