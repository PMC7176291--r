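---
title: "Methods: stochastic eco-evolutionary dynamics under periodic antimicrobial exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic eco-evolutionary dynamics under periodic antimicrobial exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amrcycle)
```

## The model

`amrcycle` models a microbial population of three genotypes on the
irreversible mutation path S → R → C:

* **S** — drug-sensitive; division rate $f_S$, death rate $g_S$ without
  drug, $f'_S$, $g'_S$ with drug;
* **R** — resistant but costly ($f_R < f_S$); unaffected by the drug;
* **C** — resistant with the cost compensated ($f_C = f_S$); unaffected
  by the drug.

Every individual divides at the logistic rate $f\,(1 - N/K)$, where $N$
is the total population size and $K$ the carrying capacity, and dies at
rate $g$. At each division exactly one daughter may mutate: S → R with
probability $\mu_1$, R → C with probability $\mu_2$; back-mutations are
neglected because compensation is reachable by many more mutations than
reversion, which also motivates the default $\mu_1 \ll \mu_2$. The
environment alternates deterministically with period $T$: drug absent on
$[kT, kT+T/2)$, present on $[kT+T/2, (k+1)T)$. Time is measured in
generations of S at low density without drug, i.e. $f_S = 1$.

A treatment *succeeds* when the population reaches $N = 0$ before the C
genotype has fixed, and *fails* otherwise. The central quantity is
$p_0$, the probability of eradication before C fixes.

Defaults (used throughout unless stated): $f_S = f_C = 1$, $f_R = 0.9$,
$g_S = g_R = g_C = 0.1$, $\mu_1 = 10^{-5}$, $\mu_2 = 10^{-3}$,
simulations start from 10 S cells (an infection bottleneck), and the
drug-strength ratio
$$\mathcal{R} = \frac{g'_S - f'_S}{g'_S}$$
is 0 exactly at the minimum inhibitory concentration (MIC), positive
above it and negative below it.

## The exact simulator

`run_trajectory()` is a Gillespie (exact stochastic simulation)
algorithm over the six event channels (division and death of each
genotype), implemented in C++ for speed but driven by R's RNG so that
`set.seed()` makes any run bit-for-bit reproducible. Two design points
deserve note:

* **Environment switches.** Propensities are piecewise constant in time
  given the state, so when the sampled waiting time would cross the next
  switch, the clock is advanced *to* the switch and the waiting time is
  re-drawn under the new rates. By memorylessness of the exponential
  distribution this is exact — no tau-leaping or discretization is
  involved.
* **Mutation at division.** The parent is never altered; the single
  daughter carries the mutation. This realizes mutation probabilities
  "per division" and gives the mutant supply rate $N \mu_1 g_S$ at
  demographic equilibrium, where the per-capita division rate equals
  $g_S$.

The boundary instant $t = kT + T/2$ itself is taken as drug-present
(half-open intervals, drug-free phase first). Nothing observable depends
on this zero-measure choice, but it fixes the convention that the first
drug addition happens *at* $T/2$. C fixation is detected at event
boundaries as $S = 0 \wedge R = 0 \wedge C > 0$; extinction as $N = 0$.
Runs that reach the safeguard `t_max` (default $10^6$) return a
`TIMEOUT` outcome which `estimate_p0()` excludes with a warning — the
Monte-Carlo aggregates are over absorbed runs only.

## The analytic layer

### Extinction times

With a perfect biostatic drug ($f'_S = 0$) the S population is a pure
death process and its mean extinction time from $N$ is the harmonic sum
$\tau_S = g_S'^{-1}\sum_{i=1}^N 1/i \approx \log(N)/g'_S$
(`tau_pure_death()`). In general, `tau_birth_death_logistic()` computes
the mean first-passage time to 0 of the chain with birth rates
$\lambda_n = f'_S n \max(0, 1-n/K)$ and death rates $\mu_n = g'_S n$ by
solving the standard tridiagonal system on $\{0,\dots,K\}$ in $O(K)$.
Because the clamped logistic rate makes $n = K$ a reflecting ceiling,
the truncation is exact, not an approximation. The result scales as
$\tau_S = \Phi(\mathcal{R})/g'_S$, which the tests verify directly.

Two thresholds organize the phase diagram:

* $T^\ast = 2\tau_S$ — above this period a single drug phase kills a
  resistance-free population (`solve_T_threshold()`);
* $\mathcal{R}^\ast$ solving $\tau_S(\mathcal{R}) = T/2$ at fixed $T$
  (`solve_R_threshold_small_period()`, bisection to
  $|\Delta\mathcal{R}| < 10^{-4}$ on $(-0.9, 0.9)$, where monotonicity
  of $\tau_S$ in $\mathcal{R}$ guarantees uniqueness).

Only *mean* extinction times are computed. The extinction time is
genuinely dispersed (roughly exponential when a quasi-stationary state
exists), so a population with $\tau_S > T/2$ can still die within a
half-period with appreciable probability $p$, and then goes extinct
after $\sim 1/p$ periods; `estimate_half_period_extinction_prob()`
measures $p$ by simulation. This is why simulated extinction regions
extend somewhat below the $T/2 = \tau_S$ line.

### Moran quantities

Before drug is added the population sits at the equilibrium
$N = K(1 - g_S/f_S)$, so resistant-lineage statistics are computed in a
fixed-size Moran frame: individuals die at their genotype rate and are
replaced by the offspring of a fitness-weighted parent. With mutant
count $j$, the step-bias ratio (down-rate over up-rate) is the constant
$q = f_{\mathrm{res}} g_{\mathrm{mut}} / (f_{\mathrm{mut}}
g_{\mathrm{res}})$, giving the fixation probability
$(1-q)/(1-q^N)$ (`fixation_probability()`), continuous at $q = 1$ where
it equals $1/N$.

`lineage_stats()` returns the expected sojourn time of a single-founder
lineage at each copy number $i$ (adjoint tridiagonal solve), the total
lifetime $\tau_d$, and the occupancy distribution
$p_{Rc}(i) = \tau_{R,i}/\tau_d$ — the distribution of the number of
preexisting resistant copies at the moment drug is added, given at
least one. The default conditions the lineage on eventual loss (Doob
h-transform with the absorption-at-0 probability, which leaves the total
exit rates unchanged because the h-function is harmonic); the
unconditioned variant is exposed as `conditioning = "none"`. For the
deleterious mutants and sizes of interest the two agree to well under a
percent — at $N = 900$ with the default rates both give
$\tau_d = `r round(lineage_stats(moran_spec(900, 1, 0.1, 0.9, 0.1))$tau_d, 3)`$
versus
$`r round(lineage_stats(moran_spec(900, 1, 0.1, 0.9, 0.1), "none")$tau_d, 3)`$
unconditioned — because fixation from one copy is vanishingly rare;
conditioning matters in principle and both variants are tested against
independent dense-matrix oracles.

From these, the probability that a resistant mutant preexists at drug
addition is $p_R = N \mu_1 g_S \tau_d$ (`p_preexisting()`, valid in the
rare-mutation regime $K\mu_1 \ll 1$, warned about beyond it), the mean
waiting time for a mutant destined to fix is
$t_{Ra} = 1/(N \mu_1 g_{\mathrm{div}}\, p_{\mathrm{fix}})$
(`appearance_fixation_time()`), and the spontaneous (drug-free)
valley-crossing time by stochastic tunneling is
$\tau_V \approx (f_S - f_R)/(\mu_1 \mu_2 g_S)$
(`valley_crossing_time()`), $10^8$ at the defaults — the ceiling of the
useful period range.

### Branching-process rescue probabilities

During a kill phase the S population is approximated deterministically:
$S(t) = S_0 e^{-g'_S t}$ for a perfect biostatic, otherwise the
closed-form solution of $\dot S = f'_S S (1 - S/K) - g'_S S$
(`deterministic_decay()`, `s_of_t()`). A resistant lineage atop this
background divides at $f_R (1 - S(t)/K)$ — the mutants' own numbers are
negligible during the early window when extinction is decided — and
dies at $g_R$. Its extinction probability is the solved form of the
time-inhomogeneous linear birth-death process,
$$p_{Re}(i) = \left[\frac{g_R I}{1 + g_R I}\right]^i,\qquad
I = \int_0^\infty e^{\rho(u)}\,du,\qquad
\rho(t) = \int_0^t \left[g_R - f_R\left(1 - \tfrac{S(u)}{K}\right)\right] du,$$
with the $i$-th power expressing independence of the $i$ sub-lineages
(`p_extinct_lineage()`; `rho()` is evaluated in closed form since
$\int S$ has one for every decay branch). For a mutant arising at time
$t_0$ into the kill phase the exponent simply restarts at $t_0$
(`p_extinct_lineage_after()`).

Numerical policy for the improper integrals: the integrand eventually
decays exactly like $e^{-(f_R-g_R)u}$, so the quadrature is truncated at
the time $S(t)$ has fallen to $10^{-9}$ of a cell plus a
$40/(f_R-g_R)$ tail window, the analytic exponential tail is added, and
the result is re-checked under horizon doubling to a relative $10^{-8}$.
When $f_R \le g_R$ the lineage is subcritical outright and the
extinction probability is set to 1 without quadrature.

### Assembled eradication probabilities

In the window $\tau_S \ll T/2 \ll \tau_V$ the population survives the
first drug addition only through resistance, and

$$p_0 = \underbrace{\Big[1 - p_R \textstyle\sum_{i=1}^{N-1} p_{Rc}(i)\,
\big(1 - p_{Re}(i)\big)\Big]}_{\text{preexisting mutants}}\;
\underbrace{\Big[1 - p_{Ra}\,\big(1 - p'_{Re}\big)\Big]}_{\text{mutants arising under drug}}$$

(`p0_eq4()`; `p0_eq1()` is the perfect-biostatic special case where the
second factor is identically 1). The de-novo appearance probability is
$p_{Ra} = N_{\mathrm{div}}\,\mu_1$ with
$N_{\mathrm{div}} = \int_0^{\tau_S} f'_S (1 - S(t)/K)\, S(t)\,dt$
(`n_div()`) the expected number of divisions in the decaying S
population — note the *drug-phase* division rate $f'_S$ in the
integrand: the integral covers the drug phase, and consistency demands
$N_{\mathrm{div}} = 0$ for a perfect biostatic, which is exactly why
such drugs close this rescue route. The upper limit is the mean
extinction time $\tau_S$; an infinite-horizon variant is available via
`tau_S = Inf` for sensitivity checks (it changes $N_{\mathrm{div}}$
only in the final, nearly-extinct tail). $p'_{Re}$ averages
`p_extinct_lineage_after()` over the appearance-time density
$\wp(t_0) \propto S(t_0)(1 - S(t_0)/K)$ (`p_extinct_denovo_avg()`).

The sum over $i$ runs to $N-1$ with all terms computed densely
($N \le 10^4$ by contract; beyond that the solvers refuse rather than
silently approximate). $N$ and all other population sizes are rounded
half-up — this matters only for tiny $K$.

## Choice of the sub-MIC demonstration parameterization

Mapping a drug-strength ratio back to rates is convention-bound:
`params_at_ratio()` fixes *biostatic* as $g'_S = g_S$, $f'_S =
g_S(1-\mathcal{R})$ and *biocidal* as $f'_S = f_S$, $g'_S =
f_S/(1-\mathcal{R})$. Because $\tau_S = \Phi(\mathcal{R})/g'_S$, the two
conventions give extinction times an order of magnitude apart at the
same $\mathcal{R}$ (the biostatic $g'_S$ is $g_S = 0.1$). The package's
headline sub-MIC experiments (the acceptance script and criteria 1–3 of
the test suite) use the **biostatic** convention: at $K = 100$,
$T = 10^{2.5}$ it places the single-phase-kill threshold at
$\mathcal{R}^\ast \approx 0.054$, gives a half-period kill probability
$p \approx 0.28$ at $\mathcal{R} = -0.1$ (hence eradication after
$\sim 3$ periods), and an overall $p_0 \approx 0.99$ — an internally
consistent trio that the biocidal convention cannot produce (its
$\tau_S$ at $\mathcal{R} = -0.1$ is $\approx 30 \ll T/2$, forcing
$p \to 1$).

## What the synthetic world does and does not establish

All inputs are parameter sets; there is no empirical data. The
generator *is* the model: exponential waiting times, well-mixed
population, constant rates within a phase, deterministic periodic
switching, one irreversible mutation path. A green test therefore
establishes internal consistency — simulator against closed forms,
closed forms against independent oracles (dense fundamental-matrix
solves, brute-force small chains, thinning-based lineage simulations,
RK4 integration) — not fidelity to any particular organism. Real
populations add spatial structure, horizontal gene transfer,
pharmacokinetic concentration profiles, tolerance/persistence phenotypes
and density-dependent drug efficacy, all deliberately out of scope.

Monte-Carlo scales are chosen for a single CPU: $10^3$ replicates per
estimate (the regime used for every quantitative claim; $10^2$ suffices
for qualitative regime checks), $\ge 10^3$ replicates in the acceptance
script, lineage oracles at $10^4$–$10^5$. Binomial uncertainty is
reported as 95% Wilson intervals; cross-validation tests use 2–3
standard-error bands.

## Known limitations

* The analytic $p_0$ assumes rare mutations ($K\mu_1 \ll 1$) and at
  most one de-novo mutant per kill phase ($N_{\mathrm{div}}\mu_1 \ll 1$);
  both assumptions are warned about, not enforced.
* Mean-based thresholds ignore extinction-time dispersion (see above);
  the simulated transition sits below the $T/2 = \tau_S$ line.
* Dense solves cap population sizes at $10^4$; larger $K$ requires a
  sparse/asymptotic treatment not implemented here.
* The default heatmap lattices (8–12 log-spaced periods, 10–15 ratios)
  are a display choice, not a contract.
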