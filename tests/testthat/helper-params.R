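# shared fixtures: the baseline parameter set (fS = 1, fR = 0.9, fC = 1,
# gS = gR = gC = 0.1, mu1 = 1e-5, mu2 = 1e-3) in its common drug variants

baseline_biostatic <- function(K) model_params(K = K, fS_drug = 0)

baseline_biocidal <- function(K, gS_drug) {
  model_params(K = K, fS_drug = 1, gS_drug = gS_drug)
}

# binomial standard error at estimate p over n replicates
se_p <- function(p, n) sqrt(p * (1 - p) / n)

# dense-matrix sojourn-time oracle for the two-type Moran lineage chain:
# expected time in each transient state 1..N-1 starting from one mutant,
# from the full generator (independent of the package's O(N) solver)
moran_sojourn_dense <- function(N, f_res, g_res, f_mut, g_mut,
                                conditioned = FALSE) {
  j <- seq_len(N - 1)
  w <- f_mut * j + f_res * (N - j)
  lam <- g_res * (N - j) * f_mut * j / w
  mu <- g_mut * j * f_res * (N - j) / w
  if (conditioned) {
    q <- (f_res * g_mut) / (f_mut * g_res)
    h <- function(k) {
      if (q == 1) return((N - k) / N)
      (q^k - q^N) / (1 - q^N)
    }
    hj <- vapply(0:N, h, numeric(1))
    lam <- lam * hj[j + 2] / hj[j + 1]
    mu <- mu * hj[j] / hj[j + 1]
  }
  Q <- matrix(0, N - 1, N - 1)
  for (i in j) {
    Q[i, i] <- -(lam[i] + mu[i])
    if (i < N - 1) Q[i, i + 1] <- lam[i]
    if (i > 1) Q[i, i - 1] <- mu[i]
  }
  solve(-t(Q), c(1, rep(0, N - 2)))
}
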