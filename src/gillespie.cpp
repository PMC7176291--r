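// Exact event-driven simulation of the three-genotype (S, R, C)
// birth-death-mutation process with logistic division rates under a
// periodic antimicrobial schedule, plus a thinning-based simulator for a
// single resistant lineage on top of a deterministically decaying
// sensitive background (used as an independent oracle for the
// branching-process survival probabilities).
//
// All randomness comes from R's RNG stream (unif_rand / exp_rand), so
// set.seed() at the R level makes every run bit-for-bit reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// outcome codes, kept in sync with .outcome_labels() in R/gillespie.R
enum OutcomeKind { EXTINCT = 0, C_FIXED = 1, TIMEOUT = 2 };

// schedule modes
enum SchedMode { PERIODIC = 0, ALWAYS_OFF = 1, ALWAYS_ON = 2 };

struct Recorder {
  int mode;            // 0 none, 1 full (every event), 2 sampled
  double sample_dt;
  int max_records;
  bool truncated;
  std::vector<double> t, S, R, C, drug;
  double next_sample;

  Recorder(int mode_, double dt_, int max_)
      : mode(mode_), sample_dt(dt_), max_records(max_), truncated(false),
        next_sample(0.0) {}

  void push(double tt, double s, double r, double c, bool on) {
    if ((int)t.size() >= max_records) { truncated = true; return; }
    t.push_back(tt); S.push_back(s); R.push_back(r); C.push_back(c);
    drug.push_back(on ? 1.0 : 0.0);
  }
};

} // namespace

// [[Rcpp::export(name = ".gillespie_run_cpp")]]
List gillespie_run_cpp(NumericVector fit_off, NumericVector death_off,
                       NumericVector fit_on, NumericVector death_on,
                       double K, double mu1, double mu2,
                       double period, int sched_mode,
                       double S0, double R0, double C0,
                       double t_max,
                       int record_mode, double sample_dt, int max_records) {
  double S = S0, R = R0, C = C0;
  double t = 0.0;

  bool drug_on = (sched_mode == ALWAYS_ON);
  double half = period / 2.0;
  // next environment switch; +Inf when the environment is constant
  double next_switch = (sched_mode == PERIODIC) ? half : R_PosInf;

  Recorder rec(record_mode, sample_dt, max_records);
  if (rec.mode != 0) rec.push(t, S, R, C, drug_on);
  if (rec.mode == 2) rec.next_sample = sample_dt;

  int kind = TIMEOUT;
  double t_event = NA_REAL;
  double n_events = 0.0;

  if (S + R + C <= 0.0) {
    kind = EXTINCT;
    t_event = 0.0;
  } else {
    for (;;) {
      const double N = S + R + C;
      const double L = (N >= K) ? 0.0 : (1.0 - N / K);
      const double fS = drug_on ? fit_on[0] : fit_off[0];
      const double fR = drug_on ? fit_on[1] : fit_off[1];
      const double fC = drug_on ? fit_on[2] : fit_off[2];
      const double gS = drug_on ? death_on[0] : death_off[0];
      const double gR = drug_on ? death_on[1] : death_off[1];
      const double gC = drug_on ? death_on[2] : death_off[2];

      const double bS = fS * L * S, bR = fR * L * R, bC = fC * L * C;
      const double dS = gS * S, dR = gR * R, dC = gC * C;
      const double total = bS + bR + bC + dS + dR + dC;

      if (total <= 0.0) {
        // frozen state: nothing can happen until the environment changes
        if (!R_finite(next_switch) || next_switch >= t_max) { t = t_max; break; }
        t = next_switch;
        drug_on = !drug_on;
        next_switch += half;
        continue;
      }

      const double dt = exp_rand() / total;
      if (t + dt >= next_switch) {
        // propensities are piecewise-constant: advance to the switch and
        // re-draw under the new rates (exact by memorylessness)
        t = next_switch;
        if (t >= t_max) break;
        drug_on = !drug_on;
        next_switch += half;
        continue;
      }
      if (t + dt >= t_max) { t = t_max; break; }
      t += dt;
      n_events += 1.0;

      double u = unif_rand() * total;
      if (u < bS) {
        // S division: one daughter, mutates to R with prob mu1
        if (unif_rand() < mu1) R += 1.0; else S += 1.0;
      } else if (u < bS + bR) {
        if (unif_rand() < mu2) C += 1.0; else R += 1.0;
      } else if (u < bS + bR + bC) {
        C += 1.0;
      } else if (u < bS + bR + bC + dS) {
        S -= 1.0;
      } else if (u < bS + bR + bC + dS + dR) {
        R -= 1.0;
      } else {
        C -= 1.0;
      }

      if (rec.mode == 1) {
        rec.push(t, S, R, C, drug_on);
      } else if (rec.mode == 2) {
        while (rec.next_sample <= t) {
          rec.push(rec.next_sample, S, R, C, drug_on);
          rec.next_sample += rec.sample_dt;
        }
      }

      if (S + R + C <= 0.0) { kind = EXTINCT; t_event = t; break; }
      if (S <= 0.0 && R <= 0.0 && C > 0.0) { kind = C_FIXED; t_event = t; break; }
    }
  }

  List out = List::create(
      _["kind"] = kind, _["t_event"] = t_event, _["t_end"] = t,
      _["S"] = S, _["R"] = R, _["C"] = C, _["n_events"] = n_events,
      _["truncated"] = rec.truncated);
  if (rec.mode != 0) {
    out["traj"] = DataFrame::create(
        _["t"] = rec.t, _["S"] = rec.S, _["R"] = rec.R, _["C"] = rec.C,
        _["drug_on"] = rec.drug);
  }
  return out;
}

// Deterministic sensitive background S(t) used by the lineage simulator.
// type 0: pure-death decay S0*exp(-g*t) (perfect biostatic).
// type 1: logistic-with-death closed form, a = f'-g', b = f'/K.
static inline double s_background(double tt, int type, double S0, double K,
                                  double fp, double gp) {
  if (S0 <= 0.0) return 0.0;
  if (type == 0) return S0 * std::exp(-gp * tt);
  const double a = fp - gp, b = fp / K;
  if (std::abs(a) < 1e-14) return S0 / (1.0 + b * S0 * tt);
  const double e = std::exp(a * tt);
  return a * S0 * e / (a + b * S0 * (e - 1.0));
}

// Simulate n_rep independent single-R lineages (birth rate fR*(1-S(t)/K)
// per head, death rate gR per head) atop the deterministic S(t), by
// thinning with per-head bound fR + gR.  A lineage counts as extinct if
// it hits 0; reaching n_cap counts as survival (for supercritical
// lineages the residual extinction probability (gR/fR)^n_cap is
// negligible at the default cap).  Returns the number extinct.
// [[Rcpp::export(name = ".sim_r_lineages_cpp")]]
int sim_r_lineages_cpp(int n_rep, double fR, double gR,
                       int decay_type, double S0, double K,
                       double fp, double gp,
                       double t0, int n_cap, double t_safeguard) {
  int n_extinct = 0;
  for (int rep = 0; rep < n_rep; ++rep) {
    double n = 1.0, tt = t0;
    const double per_head = fR + gR;
    for (;;) {
      tt += exp_rand() / (n * per_head);
      if (tt > t_safeguard) break; // count as survived (safeguard)
      const double u = unif_rand() * per_head;
      if (u < gR) {
        n -= 1.0;
        if (n <= 0.0) { ++n_extinct; break; }
      } else {
        const double Sb = s_background(tt, decay_type, S0, K, fp, gp);
        const double L = (Sb >= K) ? 0.0 : (1.0 - Sb / K);
        if (u < gR + fR * L) {
          n += 1.0;
          if (n >= n_cap) break; // survived
        }
        // else: thinning rejection, no event
      }
    }
  }
  return n_extinct;
}
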