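test_that("rho: anchors and closed form vs quadrature, both decay branches", {
  d <- deterministic_decay(0, 0.1, 1000, S0 = 900)
  expect_identical(rho(0, d, 0.9, 0.1), 0)

  d0 <- deterministic_decay(0, 0.1, 1000, S0 = 0)
  expect_equal(rho(c(1, 5), d0, 0.9, 0.1), (0.1 - 0.9) * c(1, 5))

  for (dec in list(deterministic_decay(0, 0.1, 1000, S0 = 900),
                   deterministic_decay(1, 1.1, 1000, S0 = 900),
                   deterministic_decay(1, 1, 100, S0 = 90))) {
    for (t in c(0.5, 5, 30)) {
      quad <- stats::integrate(function(u)
        0.1 - 0.9 * (1 - s_of_t(dec, u) / dec$K), 0, t,
        rel.tol = 1e-10)$value
      expect_equal(rho(t, dec, 0.9, 0.1), quad, tolerance = 1e-8)
    }
  }
})

test_that("lineage extinction probability: limits and power structure", {
  d <- deterministic_decay(0, 0.1, 1000, S0 = 900)
  # subcritical lineage dies for sure
  expect_identical(p_extinct_lineage(1, d, 0.05, 0.1), 1)
  # constant-rate limit gR/fR
  d0 <- deterministic_decay(0, 0.1, 1000, S0 = 0)
  expect_equal(p_extinct_lineage(1, d0, 0.9, 0.1), 1 / 9, tolerance = 1e-8)
  # independence of sub-lineages: pRe(i) = pRe(1)^i
  p1 <- p_extinct_lineage(1, d, 0.9, 0.1)
  i <- c(2, 3, 7, 20)
  expect_equal(p_extinct_lineage(i, d, 0.9, 0.1), p1^i, tolerance = 1e-10)
  expect_true(p1 > 1 / 9 && p1 < 1)  # competition can only raise extinction
})

test_that("lineage extinction vs branching simulation (biostatic decay)", {
  d <- deterministic_decay(0, 0.1, 1000, S0 = 900)
  p1 <- p_extinct_lineage(1, d, 0.9, 0.1)
  frac <- sim_lineage_extinction_fraction(5e4, d, 0.9, 0.1, seed = 81)
  expect_lt(abs(frac - p1), 2 * se_p(p1, 5e4) + 2e-3)
})

test_that("post-addition extinction probability p'Re(t0)", {
  db <- deterministic_decay(1, 2, 1000, S0 = 900)
  # t0 = 0 coincides with the preexisting-lineage case at i = 1
  expect_equal(p_extinct_lineage_after(0, db, 0.9, 0.1),
               p_extinct_lineage(1, db, 0.9, 0.1), tolerance = 1e-9)
  # t0 -> infinity: background gone, constant-rate limit
  expect_equal(p_extinct_lineage_after(500, db, 0.9, 0.1), 1 / 9,
               tolerance = 1e-6)
  # decreasing in t0: later mutants find more free capacity
  t0s <- c(0, 1, 3, 10)
  ps <- p_extinct_lineage_after(t0s, db, 0.9, 0.1)
  expect_true(all(diff(ps) < 0))
  # simulation oracle at t0 = 5
  p5 <- p_extinct_lineage_after(5, db, 0.9, 0.1)
  frac <- sim_lineage_extinction_fraction(5e4, db, 0.9, 0.1, t0 = 5, seed = 82)
  expect_lt(abs(frac - p5), 2 * se_p(p5, 5e4) + 2e-3)
})

test_that("appearance-averaged de-novo extinction probability", {
  db <- deterministic_decay(1, 1.1, 1000, S0 = 900)
  pavg <- p_extinct_denovo_avg(db, baseline_biocidal(1000, 1.1))
  p_range <- p_extinct_lineage_after(c(0, 200), db, 0.9, 0.1)
  expect_true(pavg < p_range[1] && pavg > 1 / 9)  # between endpoints

  # end-to-end stochastic oracle: seed mutants at simulated division
  # times of the decaying pure-S population, then run each lineage
  p <- baseline_biocidal(1000, 1.1)
  p$mu1 <- 0
  cfg <- sim_config(p, alternation_schedule(mode = "always_on"),
                    init = c(S = 900, R = 0, C = 0), record = "full",
                    max_records = 2e6)
  withr::with_seed(83, {
    extinct <- 0L; total <- 0L
    for (rep in 1:6) {
      tr <- run_trajectory(cfg)$traj
      birth_t <- tr$t[c(FALSE, diff(tr$S) > 0)]
      t0s <- sample(birth_t, 400, replace = TRUE)
      for (t0 in t0s) {
        total <- total + 1L
        ext <- sim_lineage_extinction_fraction(1, db, 0.9, 0.1, t0 = t0)
        extinct <- extinct + as.integer(ext)
      }
    }
  })
  frac <- extinct / total
  expect_lt(abs(frac - pavg), 2 * se_p(pavg, total) + 0.01)
})

test_that("p0 assembly: degenerate and limiting cases", {
  # no mutation: pR = 0, extinction certain
  p <- baseline_biostatic(1000)
  p$mu1 <- 0
  expect_identical(p0_eq1(p)$p0, 1)

  # eq4 with a perfect biostatic reduces exactly to eq1
  pb <- baseline_biostatic(1000)
  expect_equal(p0_eq4(pb)$p0, p0_eq1(pb)$p0, tolerance = 1e-12)
  expect_identical(p0_eq4(pb)$pRa, 0)

  # eq1 demands a perfect biostatic; eq4 demands above-MIC
  expect_error(p0_eq1(baseline_biocidal(100, 1.1)), "perfect biostatic")
  expect_error(p0_eq4(params_at_ratio(-0.1, model_params(K = 100), "biocidal")),
               "above-MIC")
})

test_that("p0 orderings across drug mode, strength and population size", {
  # larger kill rate -> larger p0 (fewer divisions under drug)
  p11 <- p0_eq4(baseline_biocidal(1000, 1.1))
  p20 <- p0_eq4(baseline_biocidal(1000, 2))
  expect_gt(p20$p0, p11$p0)
  expect_gt(p11$pRa, p20$pRa)

  # perfect biostatic beats the hard-kill biocidal limit (competition effect)
  pstat <- p0_eq1(baseline_biostatic(1000))
  pcide <- p0_eq4(baseline_biocidal(1000, 1000))
  expect_gte(pstat$p0, pcide$p0)

  # p0 decreases with K (more mutant supply)
  p0s <- vapply(c(100, 1000, 1e4), function(K) {
    suppressWarnings(p0_eq1(baseline_biostatic(K))$p0)
  }, numeric(1))
  expect_true(all(diff(p0s) < 0))

  # assembled probabilities stay in [0, 1]; second factor <= first
  pred <- p0_eq4(baseline_biocidal(1000, 1.1))
  first <- 1 - pred$pR * sum(pred$pRc * (1 - pred$pRe1^seq_along(pred$pRc)))
  expect_true(pred$p0 >= 0 && pred$p0 <= 1)
  expect_lte(pred$p0, first + 1e-12)
})
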