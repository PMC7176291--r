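test_that("fixation probability: anchors, neutrality, continuity, bounds", {
  expect_equal(fixation_probability(moran_spec(10, 1, 0.1, 1, 0.1)), 0.1)
  # fast-alternation resident f~S = 0.5 vs resistant mutant 0.9
  expect_equal(fixation_probability(moran_spec(800, 0.5, 0.1, 0.9, 0.1)),
               (1 - 5 / 9) / (1 - (5 / 9)^800), tolerance = 1e-12)
  # sub-MIC: q = f'S gR / (fR g'S)
  expect_equal(fixation_probability(moran_spec(500, 1, 0.5, 0.9, 0.1)),
               (1 - 2 / 9) / (1 - (2 / 9)^500), tolerance = 1e-12)

  # continuity at q = 1: no cancellation blow-up as q -> 1 from either side
  N <- 50
  for (eps in c(-1e-9, 1e-9)) {
    p <- fixation_probability(moran_spec(N, 1, 0.1, 1 + eps, 0.1))
    expect_lt(abs(p - 1 / N), 1e-9)
  }
  ps <- vapply(c(1e-4, 1e-6, 1e-8), function(eps)
    fixation_probability(moran_spec(N, 1, 0.1, 1 + eps, 0.1)), numeric(1))
  expect_true(all(abs(ps - 1 / N) < abs(ps[1] - 1 / N) * c(1, 1e-1, 1e-3) + 1e-12))

  # strictly decreasing in q, bounded in (0,1)
  ps <- vapply(c(0.5, 0.8, 1, 1.25, 2),
               function(fr) fixation_probability(moran_spec(30, fr, 0.1, 1, 0.1)),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("lineage sojourn times match the dense fundamental-matrix oracle", {
  spec <- moran_spec(5, 1, 0.1, 0.9, 0.1)
  for (cond in c(FALSE, TRUE)) {
    oracle <- moran_sojourn_dense(5, 1, 0.1, 0.9, 0.1, conditioned = cond)
    got <- lineage_stats(spec, conditioning = if (cond) "extinction" else "none")
    expect_equal(got$sojourn, oracle, tolerance = 1e-8)
    expect_equal(sum(got$pRc), 1, tolerance = 1e-10)
  }
})

test_that("lineage lifetime matches direct stochastic lineage simulation", {
  # vectorized jump-chain simulation of 2e4 single-mutant lineages, N = 5
  N <- 5
  f_res <- 1; g_res <- 0.1; f_mut <- 0.9; g_mut <- 0.1
  j <- 1:(N - 1)
  w <- f_mut * j + f_res * (N - j)
  lam <- g_res * (N - j) * f_mut * j / w
  mu <- g_mut * j * f_res * (N - j) / w
  M <- 2e4
  withr::with_seed(71, {
    state <- rep(1L, M); life <- numeric(M)
    while (any(alive <- state > 0 & state < N)) {
      idx <- which(alive)
      s <- state[idx]
      rate <- lam[s] + mu[s]
      life[idx] <- life[idx] + stats::rexp(length(idx), rate)
      up <- stats::runif(length(idx)) < lam[s] / rate
      state[idx] <- s + ifelse(up, 1L, -1L)
    }
  })
  st_unc <- lineage_stats(moran_spec(N, f_res, g_res, f_mut, g_mut), "none")
  expect_lt(abs(mean(life) - st_unc$tau_d), 3 * stats::sd(life) / sqrt(M))
  # extinction-conditioned lifetime = mean among lineages absorbed at 0
  lost <- life[state == 0]
  st_ext <- lineage_stats(moran_spec(N, f_res, g_res, f_mut, g_mut))
  expect_lt(abs(mean(lost) - st_ext$tau_d),
            3 * stats::sd(lost) / sqrt(length(lost)))
})

test_that("occupancy distribution decreases with copy number (deleterious)", {
  for (N in c(10, 90, 900)) {
    pRc <- lineage_stats(moran_spec(N, 1, 0.1, 0.9, 0.1))$pRc
    expect_true(all(diff(pRc) < 0))
  }
})

test_that("p_preexisting: arithmetic, linearity, caps and warnings", {
  st <- lineage_stats(moran_spec(900, 1, 0.1, 0.9, 0.1))
  expect_identical(p_preexisting(900, 0, 0.1, st), 0)
  pR <- p_preexisting(900, 1e-5, 0.1, st)
  expect_equal(pR, st$tau_d / (1 / (900 * 1e-5 * 0.1)))
  expect_true(pR > 0 && pR < 1)
  expect_equal(p_preexisting(900, 2e-5, 0.1, st), 2 * pR)
  expect_warning(p_preexisting(900, 2e-4, 0.1, st), "rare-mutation")
  fake <- list(tau_d = 1e9)
  expect_warning(out <- p_preexisting(900, 1e-5, 0.1, fake), "capped")
  expect_identical(out, 1)
})

test_that("appearance/fixation waiting time and valley crossing", {
  pfix <- fixation_probability(moran_spec(800, 0.5, 0.1, 0.9, 0.1))
  expect_equal(appearance_fixation_time(800, 1e-5, 0.1, pfix),
               1 / (800 * 1e-5 * 0.1 * pfix))  # ~2813
  expect_equal(appearance_fixation_time(800, 1e-5, 0.1, pfix), 2813,
               tolerance = 1e-3)
  expect_identical(appearance_fixation_time(800, 0, 0.1, 0.5), Inf)
  pfix2 <- fixation_probability(moran_spec(500, 1, 0.5, 0.9, 0.1))
  expect_equal(appearance_fixation_time(500, 1e-5, 0.5, pfix2), 514.3,
               tolerance = 1e-3)

  p <- model_params(K = 1000)
  expect_equal(valley_crossing_time(p), 1e8)
  p2 <- model_params(K = 1000, mu2 = 1e-2)
  expect_equal(valley_crossing_time(p2), 1e7)
  expect_error(valley_crossing_time(model_params(K = 10, fR = 1)), "valley")
})
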