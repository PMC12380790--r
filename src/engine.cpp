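// Compiled simulation core. Implements the identical per-step algorithm
// as the R engines (see R/engine.R for the contract): delayed PSC
// aggregation, current summation, noisy Euler neuron stepping with reset,
// Tsodyks-Markram relaxation + spike jumps, delay-buffer push.
//
// Arithmetic is ordered to match the scalar R reference bit-for-bit:
// per-target accumulation runs over ascending source indices (the
// column-sweep below preserves that order element-wise), and compound
// expressions are parenthesized exactly as R evaluates them.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Projection {
  int tj, sj, k;
  NumericMatrix W;   // n_target x n_source
  double mix[3];
};

inline int mod_pos(int a, int m) {
  int r = a % m;
  return r < 0 ? r + m : r;
}

}  // namespace

// [[Rcpp::export]]
List run_tcm_cpp(int n_steps, double dt,
                 IntegerVector n_per, IntegerVector offsets,
                 NumericVector a, NumericVector b, NumericVector c_,
                 NumericVector d, NumericVector v_peak, NumericVector bias,
                 NumericVector v0, NumericVector u0,
                 List proj, List tm_par, int n_hist,
                 NumericVector dbs_wave, int dbs_target,
                 double sigma_xi, double sigma_zeta, bool per_step,
                 bool bg_enabled, NumericVector bg_rate, NumericVector bg_amp,
                 int seed_membrane, int seed_threshold, int seed_background,
                 bool record_traces,
                 NumericMatrix xi_stream, NumericMatrix zeta_stream) {
  const int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());

  // projections
  std::vector<Projection> P;
  for (int p = 0; p < proj.size(); ++p) {
    List pl = proj[p];
    Projection pr;
    pr.tj = as<int>(pl["tj"]);
    pr.sj = as<int>(pl["sj"]);
    pr.k = as<int>(pl["k"]);
    pr.W = as<NumericMatrix>(pl["W"]);
    NumericVector m = pl["mix"];
    for (int ci = 0; ci < 3; ++ci) pr.mix[ci] = m[ci];
    P.push_back(pr);
  }

  // TM parameters per structure per class (precomputed decay factors)
  double eF[6][3], eD[6][3], eS[6][3], Upar[6][3], Apar[6][3];
  for (int sj = 0; sj < 6; ++sj) {
    List cls = tm_par[sj];
    for (int ci = 0; ci < 3; ++ci) {
      NumericVector pv = cls[ci];
      Upar[sj][ci] = pv["U"];
      eF[sj][ci] = std::exp(-dt / as<double>(pv["tau_f"]));
      eD[sj][ci] = std::exp(-dt / as<double>(pv["tau_d"]));
      eS[sj][ci] = std::exp(-dt / as<double>(pv["tau_s"]));
      Apar[sj][ci] = pv["A"];
    }
  }

  // TM state and circular PSC-history buffers: [structure][class]
  std::vector<std::vector<double>> tm_u(18), tm_x(18), tm_I(18), buf(18);
  for (int sj = 0; sj < 6; ++sj)
    for (int ci = 0; ci < 3; ++ci) {
      int id = sj * 3 + ci, ns = n_per[sj];
      tm_u[id].assign(ns, 0.0);
      tm_x[id].assign(ns, 1.0);
      tm_I[id].assign(ns, 0.0);
      buf[id].assign((size_t)n_hist * ns, 0.0);
    }

  const bool have_xi_stream = xi_stream.nrow() > 0;
  const bool have_zeta_stream = zeta_stream.nrow() > 0;
  const bool use_xi = sigma_xi > 0 || have_xi_stream;
  const bool use_zeta = sigma_zeta > 0 || have_zeta_stream;
  const double xi_scale = per_step ? sigma_xi : sigma_xi * std::sqrt(dt);

  std::mt19937_64 rng_xi((uint64_t)(unsigned)seed_membrane);
  std::mt19937_64 rng_zeta((uint64_t)(unsigned)seed_threshold);
  std::mt19937_64 rng_bg((uint64_t)(unsigned)seed_background);
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> spike_id, spike_step;
  NumericMatrix mean_v(record_traces ? n_steps : 0, record_traces ? 6 : 0);

  std::vector<double> I_syn(n), eff, acc_proj, xi(n), zeta(n), vrec(n);
  std::vector<char> spiked(n);
  const int tgt_lo = offsets[dbs_target];
  const int tgt_hi = offsets[dbs_target] + n_per[dbs_target];  // exclusive

  for (int s = 1; s <= n_steps; ++s) {
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();

    // noise draws (dedicated substreams; order fixed per step)
    if (use_xi) {
      if (have_xi_stream)
        for (int i = 0; i < n; ++i) xi[i] = xi_stream(s - 1, i);
      else
        for (int i = 0; i < n; ++i) xi[i] = norm(rng_xi);
    }
    if (use_zeta) {
      if (have_zeta_stream)
        for (int i = 0; i < n; ++i) zeta[i] = zeta_stream(s - 1, i);
      else
        for (int i = 0; i < n; ++i) zeta[i] = norm(rng_zeta);
    }

    // (1) delayed PSC aggregation
    std::fill(I_syn.begin(), I_syn.end(), 0.0);
    for (const Projection& pr : P) {
      const int ns_src = n_per[pr.sj], nt = n_per[pr.tj];
      const int row = mod_pos(s - pr.k - 1, n_hist);
      eff.assign(ns_src, 0.0);
      for (int ci = 0; ci < 3; ++ci) {
        const double f = pr.mix[ci];
        if (f > 0) {
          const double* bp = buf[pr.sj * 3 + ci].data() + (size_t)row * ns_src;
          for (int is = 0; is < ns_src; ++is) eff[is] += f * bp[is];
        }
      }
      // column sweep into a per-projection accumulator: per target
      // element the source terms accumulate in ascending order starting
      // from zero, and the projection subtotal is added to I_syn once —
      // the exact summation order of the naive scalar reference
      acc_proj.assign(nt, 0.0);
      for (int is = 0; is < ns_src; ++is) {
        const double e = eff[is];
        if (e == 0.0) continue;
        const double* col = pr.W.begin() + (size_t)is * nt;
        for (int it = 0; it < nt; ++it) acc_proj[it] += col[it] * e;
      }
      double* out = I_syn.data() + offsets[pr.tj];
      for (int it = 0; it < nt; ++it) out[it] += acc_proj[it];
    }

    // (2)-(3) per-neuron current, Euler step, spike detection, reset
    const double dbs_val = dbs_wave[s - 1];
    for (int i = 0; i < n; ++i) {
      double I = bias[i] + I_syn[i];
      if (bg_enabled) {
        const double pev = bg_rate[i] * dt / 1000.0;
        if (unif(rng_bg) < pev) I = I + bg_amp[i];
      }
      if (dbs_val != 0.0 && i >= tgt_lo && i < tgt_hi) I = I + dbs_val;
      const double vi0 = v[i], ui0 = u[i];
      const double dv = 0.04 * (vi0 * vi0) + 5 * vi0 - ui0 + 140 + I;
      const double du = a[i] * (b[i] * vi0 - ui0);
      double vi = vi0 + dt * dv;
      double ui = ui0 + dt * du;
      if (use_xi) vi = vi + xi_scale * xi[i];
      if (!std::isfinite(vi) || !std::isfinite(ui))
        stop("numerical blow-up: non-finite membrane state at step %d, neuron %d",
             s, i + 1);
      double thr = v_peak[i];
      if (use_zeta) thr = thr + sigma_zeta * zeta[i];
      if (vi >= thr) {
        spiked[i] = 1;
        vrec[i] = v_peak[i];
        vi = c_[i];
        ui = ui + d[i];
      } else {
        spiked[i] = 0;
        vrec[i] = vi;
      }
      v[i] = vi;
      u[i] = ui;
    }

    // (4)-(5) TM relaxation + spike jumps, buffer push
    const int row_now = mod_pos(s - 1, n_hist);
    for (int sj = 0; sj < 6; ++sj) {
      const int ns_src = n_per[sj];
      if (ns_src == 0) continue;
      const int off_s = offsets[sj];
      for (int ci = 0; ci < 3; ++ci) {
        const int id = sj * 3 + ci;
        double* tu = tm_u[id].data();
        double* tx = tm_x[id].data();
        double* tI = tm_I[id].data();
        double* bp = buf[id].data() + (size_t)row_now * ns_src;
        const double ef = eF[sj][ci], ed = eD[sj][ci], es = eS[sj][ci];
        const double Uc = Upar[sj][ci], Ac = Apar[sj][ci];
        for (int is = 0; is < ns_src; ++is) {
          double uu = tu[is] * ef;
          double xx = 1 - (1 - tx[is]) * ed;
          double II = tI[is] * es;
          if (spiked[off_s + is]) {
            const double u1 = uu + Uc * (1 - uu);
            II = II + Ac * u1 * xx;
            xx = xx - u1 * xx;
            uu = u1;
          }
          // flush to the no-activity fixed point below 1e-12: values this
          // far into the exponential tail are physically nil and would
          // otherwise decay into (slow) subnormal arithmetic
          if (uu < 1e-12) uu = 0.0;
          if (xx > 1 - 1e-12) xx = 1.0;
          if (II < 1e-12 && II > -1e-12) II = 0.0;
          tu[is] = uu; tx[is] = xx; tI[is] = II;
          bp[is] = II;
        }
      }
    }

    // (6) record
    for (int i = 0; i < n; ++i)
      if (spiked[i]) {
        spike_id.push_back(i + 1);
        spike_step.push_back(s);
      }
    if (record_traces) {
      for (int j = 0; j < 6; ++j) {
        const int nj = n_per[j];
        if (nj == 0) { mean_v(s - 1, j) = NA_REAL; continue; }
        double acc = 0;
        for (int i = offsets[j]; i < offsets[j] + nj; ++i) acc += vrec[i];
        mean_v(s - 1, j) = acc / nj;
      }
    }
  }

  List out = List::create(
    Named("spike_id") = wrap(spike_id),
    Named("spike_step") = wrap(spike_step));
  out["mean_v"] = record_traces ? (SEXP)mean_v : R_NilValue;
  return out;
}
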