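test_that("degenerate starts: empty population, zero t_max margin", {
  p <- model_params(K = 100)
  cfg <- sim_config(p, alternation_schedule(20), init = c(S = 0, R = 0, C = 0))
  out <- run_trajectory(cfg, seed = 1)
  expect_identical(out$kind, "EXTINCT")
  expect_identical(out$t_event, 0)

  # a frozen always-on perfect-biostatic run with g = 0 can only time out
  p0 <- model_params(K = 100, gS = 0, gR = 0, gC = 0, fS_drug = 0, gS_drug = 0)
  cfg0 <- sim_config(p0, alternation_schedule(mode = "always_on"),
                     init = c(S = 5, R = 0, C = 0), t_max = 10)
  expect_identical(run_trajectory(cfg0, seed = 1)$kind, "TIMEOUT")
})

test_that("pure-death extinction times match the harmonic-sum oracle", {
  # drug always on, perfect biostatic, mu = 0: pure death process
  p <- baseline_biostatic(1000)
  p$mu1 <- 0
  cfg <- sim_config(p, alternation_schedule(mode = "always_on"),
                    init = c(S = 900, R = 0, C = 0))
  seeds <- withr::with_seed(5, sample.int(1e6, 400))
  times <- vapply(seeds, function(s) run_trajectory(cfg, seed = s)$t_event,
                  numeric(1))
  oracle <- tau_pure_death(900, 0.1)           # 73.80
  expect_lt(abs(mean(times) - oracle), 2 * stats::sd(times) / sqrt(length(times)))
})

test_that("exactness: single-individual lifetime is exponential (KS)", {
  p <- model_params(K = 10, fS_drug = 0, gS_drug = 1)
  p$mu1 <- 0
  cfg <- sim_config(p, alternation_schedule(mode = "always_on"),
                    init = c(S = 1, R = 0, C = 0))
  seeds <- withr::with_seed(17, sample.int(1e7, 1e4))
  times <- vapply(seeds, function(s) run_trajectory(cfg, seed = s)$t_event,
                  numeric(1))
  expect_gt(stats::ks.test(times, stats::pexp, rate = 1)$p.value, 0.01)
})

test_that("drug-free growth settles at the deterministic equilibrium", {
  p <- model_params(K = 1000)
  p$mu1 <- 0
  cfg <- sim_config(p, alternation_schedule(mode = "always_off"),
                    init = c(S = 10, R = 0, C = 0), t_max = 500,
                    record = "sampled", sample_dt = 1)
  out <- run_trajectory(cfg, seed = 23)
  traj <- out$traj
  late <- traj$S[traj$t >= 50]
  expect_equal(mean(late), 900, tolerance = 0.02)   # K(1 - gS/fS)
})

test_that("trajectory invariants: one-step moves, bounds, purity at mu1=0", {
  p <- baseline_biocidal(200, 1.1)
  cfg <- sim_config(p, alternation_schedule(50), init = c(S = 10, R = 0, C = 0),
                    t_max = 300, record = "full")
  out <- run_trajectory(cfg, seed = 31)
  traj <- out$traj
  expect_true(all(diff(traj$t) > 0))
  steps <- abs(diff(traj$S)) + abs(diff(traj$R)) + abs(diff(traj$C))
  expect_true(all(steps == 1))                      # one birth or death per event
  N <- traj$S + traj$R + traj$C
  expect_true(all(N >= 0) && all(N <= max(10, p$K)))
  expect_true(all(traj$S >= 0 & traj$R >= 0 & traj$C >= 0))
  # recorded environment annotation matches the schedule
  expect_identical(traj$drug_on == 1,
                   vapply(traj$t, function(t)
                     environment_at(cfg$schedule, t)$drug_on, logical(1)))

  p$mu1 <- 0
  cfg2 <- sim_config(p, alternation_schedule(50), t_max = 200, record = "full")
  tr2 <- run_trajectory(cfg2, seed = 32)$traj
  expect_true(all(tr2$R == 0) && all(tr2$C == 0))
})

test_that("identical seed and config reproduce bit-for-bit", {
  p <- baseline_biocidal(100, 1.1)
  cfg <- sim_config(p, alternation_schedule(30), t_max = 500, record = "full")
  a <- run_trajectory(cfg, seed = 99)
  b <- run_trajectory(cfg, seed = 99)
  expect_identical(a, b)
  est1 <- estimate_p0(cfg, 20, seed = 5)
  est2 <- estimate_p0(cfg, 20, seed = 5)
  expect_identical(est1, est2)
})

test_that("estimate_p0 aggregates outcomes and flags timeouts", {
  # long-period biostatic at small K: extinction near-certain
  p <- baseline_biostatic(100)
  est <- estimate_p0(sim_config(p, alternation_schedule(1000)), 50, seed = 41)
  expect_true(est$p0 >= 0 && est$p0 <= 1)
  expect_true(est$ci[["lo"]] <= est$p0 && est$p0 <= est$ci[["hi"]])
  expect_equal(sum(est$counts), 50)
  expect_gt(est$mean_t_ext, 500)       # extinction shortly after first addition

  # t_max below the first drug addition: every replicate times out
  cfg_to <- sim_config(p, alternation_schedule(1000), t_max = 100)
  expect_error(suppressWarnings(estimate_p0(cfg_to, 5, seed = 2)), "timed out")
})

test_that("half-period extinction probability: limits", {
  p <- baseline_biostatic(100)
  # perfect biostatic with T >> 2 tauS: extinction within T/2 is certain
  est <- estimate_half_period_extinction_prob(p, 10 * tau_pure_death(90, 0.1),
                                              50, seed = 43)
  expect_equal(est$p0, 1)
  # T -> 0: extinction time is strictly positive from N >= 1
  est0 <- estimate_half_period_extinction_prob(p, 1e-4, 50, seed = 44)
  expect_equal(est0$p0, 0)
})
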