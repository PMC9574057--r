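// Time-driven network engine: fixed grid (default dt = 0.05 ms), exact
// sub-threshold propagator per neuron type, ring-buffer spike delivery with
// per-synapse delays, and event-driven closed-form STP updates applied to a
// presynaptic neuron's outbound plastic synapses at emission time.
//
// The R wrapper (run_simulation) prepares all inputs: CSR connectivity by
// source neuron, precomputed current jumps (alpha * J / tau_syn, signed),
// resolved protocol epochs, and propagator inputs. Noise uses a private
// mt19937_64 stream so the run is reproducible from its seed alone.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Prop {
  double dV, cE, cI, cX;  // per-type membrane coefficients
};

inline double cross_coef(double tm, double ts, double Rm, double dt) {
  if (std::fabs(tm - ts) < 1e-12)
    return Rm * (dt / tm) * std::exp(-dt / tm);
  return Rm * (ts / (tm - ts)) * (std::exp(-dt / tm) - std::exp(-dt / ts));
}

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int n_e, int n_i,
                NumericVector tau_m,    // length 2: E, I
                NumericVector R_m,      // length 2
                NumericVector V_th,     // length 2
                NumericVector V_reset,  // length 2
                NumericVector t_ref,    // length 2
                double tau_exc, double tau_inh,
                IntegerVector out_ptr,      // length N+1, 0-based
                IntegerVector c_tgt,        // 0-based target ids
                NumericVector c_jump,       // static: full jump; plastic: jump factor
                IntegerVector c_delay,      // delay in steps, >= 1
                IntegerVector c_plastic,    // plastic id or -1
                int n_plastic,
                double U, double tau_f, double tau_d, bool post_u,
                NumericVector ep_start, NumericVector ep_end,
                NumericVector ep_mu, NumericVector ep_sigma,
                List ep_members,            // 0-based IntegerVectors
                double dt, int n_steps, double seed,
                NumericVector V0,
                bool record_spikes,
                List trace_ids,             // per traced set: plastic ids (0-based)
                int trace_every,
                IntegerVector forced_step,  // sorted ascending
                IntegerVector forced_id,    // 0-based
                bool return_stp) {
  const int N = n_e + n_i;
  const int spm = (int)std::lround(1.0 / dt);  // steps per 1 ms interval
  int max_delay = 1;
  for (int k = 0; k < c_delay.size(); ++k)
    if (c_delay[k] > max_delay) max_delay = c_delay[k];
  const int H = max_delay + 1;

  // propagator coefficients per type (0 = excitatory, 1 = inhibitory)
  Prop prop[2];
  double ref_steps_d[2];
  for (int ty = 0; ty < 2; ++ty) {
    prop[ty].dV = std::exp(-dt / tau_m[ty]);
    prop[ty].cE = cross_coef(tau_m[ty], tau_exc, R_m[ty], dt);
    prop[ty].cI = cross_coef(tau_m[ty], tau_inh, R_m[ty], dt);
    prop[ty].cX = R_m[ty] * (1.0 - prop[ty].dV);
    ref_steps_d[ty] = t_ref[ty] / dt;
  }
  const double dE = std::exp(-dt / tau_exc);
  const double dI = std::exp(-dt / tau_inh);

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> Ie(N, 0.0), Ii(N, 0.0), Ix(N, 0.0);
  std::vector<int> refr(N, 0);
  std::vector<uint8_t> type(N, 0);
  for (int j = n_e; j < N; ++j) type[j] = 1;

  std::vector<double> bufE((size_t)H * N, 0.0), bufI((size_t)H * N, 0.0);

  std::vector<double> su(n_plastic, U), sx(n_plastic, 1.0),
      st_last(n_plastic, 0.0);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> n_spikes(N, 0);
  std::vector<int> spikers;
  spikers.reserve(4096);

  const int n_ep = ep_start.size();
  std::vector<IntegerVector> members(n_ep);
  for (int e = 0; e < n_ep; ++e) members[e] = as<IntegerVector>(ep_members[e]);

  const int n_tr = trace_ids.size();
  std::vector<IntegerVector> tr(n_tr);
  for (int s = 0; s < n_tr; ++s) tr[s] = as<IntegerVector>(trace_ids[s]);
  int n_samples = (trace_every > 0) ? n_steps / trace_every + 1 : 0;
  std::vector<std::vector<double>> tr_t(n_tr), tr_u(n_tr), tr_x(n_tr);
  for (int s = 0; s < n_tr; ++s) {
    tr_t[s].reserve(n_samples);
    tr_u[s].reserve(n_samples);
    tr_x[s].reserve(n_samples);
  }

  const double inv_tf = 1.0 / tau_f, inv_td = 1.0 / tau_d;
  int fs_pos = 0;
  const int n_forced = forced_step.size();

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // refresh the piecewise-constant external currents on 1 ms boundaries
    if (step % spm == 0) {
      const double k_ms = (double)(step / spm);
      std::fill(Ix.begin(), Ix.end(), 0.0);
      for (int e = 0; e < n_ep; ++e) {
        if (k_ms >= ep_start[e] && k_ms < ep_end[e]) {
          const double mu = ep_mu[e], sg = ep_sigma[e];
          const IntegerVector& m = members[e];
          for (int q = 0; q < m.size(); ++q)
            Ix[m[q]] += mu + sg * gauss(rng);
        }
      }
      if ((step / spm) % 10 == 0) {
        for (int j = 0; j < N; ++j)
          if (!std::isfinite(V[j]))
            stop("numerical failure: non-finite V for neuron %d at t = %.2f ms",
                 j + 1, t);
        Rcpp::checkUserInterrupt();
      }
    }

    // STP trace sampling (left-side limits, analytic decay from t_last)
    if (trace_every > 0 && step % trace_every == 0) {
      for (int s = 0; s < n_tr; ++s) {
        const IntegerVector& ids = tr[s];
        double mu_ = 0.0, mx_ = 0.0;
        for (int q = 0; q < ids.size(); ++q) {
          const int p = ids[q];
          const double dtl = t - st_last[p];
          mu_ += U + (su[p] - U) * std::exp(-dtl * inv_tf);
          mx_ += 1.0 + (sx[p] - 1.0) * std::exp(-dtl * inv_td);
        }
        const double n = (double)ids.size();
        tr_t[s].push_back(t);
        tr_u[s].push_back(mu_ / n);
        tr_x[s].push_back(mx_ / n);
      }
    }

    // deliver due spikes, propagate, detect threshold crossings
    const int slot = step % H;
    double* bE = &bufE[(size_t)slot * N];
    double* bI = &bufI[(size_t)slot * N];
    spikers.clear();
    for (int j = 0; j < N; ++j) {
      double ie = Ie[j] + bE[j];
      double ii = Ii[j] + bI[j];
      bE[j] = 0.0;
      bI[j] = 0.0;
      const Prop& P = prop[type[j]];
      if (refr[j] > 0) {
        --refr[j];
        // membrane clamped at reset; currents keep evolving
      } else {
        double v = P.dV * V[j] + P.cE * ie + P.cI * ii + P.cX * Ix[j];
        if (v >= V_th[type[j]]) {
          V[j] = V_reset[type[j]];
          refr[j] = (int)std::lround(ref_steps_d[type[j]]);
          spikers.push_back(j);
        } else {
          V[j] = v;
        }
      }
      Ie[j] = dE * ie;
      Ii[j] = dI * ii;
    }

    // externally forced emissions (test instrumentation)
    while (fs_pos < n_forced && forced_step[fs_pos] == step) {
      const int j = forced_id[fs_pos];
      V[j] = V_reset[type[j]];
      refr[j] = (int)std::lround(ref_steps_d[type[j]]);
      spikers.push_back(j);
      ++fs_pos;
    }

    // process emissions: record, update outbound STP, schedule deliveries
    for (size_t a = 0; a < spikers.size(); ++a) {
      const int j = spikers[a];
      ++n_spikes[j];
      if (record_spikes) {
        spike_t.push_back(t);
        spike_id.push_back(j + 1);
      }
      const bool src_exc = (type[j] == 0);
      for (int k = out_ptr[j]; k < out_ptr[j + 1]; ++k) {
        double h = c_jump[k];
        const int p = c_plastic[k];
        if (p >= 0) {
          const double dtl = t - st_last[p];
          const double um = U + (su[p] - U) * std::exp(-dtl * inv_tf);
          const double xm = 1.0 + (sx[p] - 1.0) * std::exp(-dtl * inv_td);
          const double up = um + U * (1.0 - um);
          h *= (post_u ? up : um) * xm;
          su[p] = up;
          sx[p] = xm - up * xm;
          st_last[p] = t;
        }
        const int sl = (step + c_delay[k]) % H;
        double* buf = src_exc ? &bufE[(size_t)sl * N] : &bufI[(size_t)sl * N];
        buf[c_tgt[k]] += h;
      }
    }
  }

  List traces(n_tr);
  for (int s = 0; s < n_tr; ++s)
    traces[s] = DataFrame::create(_["time"] = tr_t[s], _["mean_u"] = tr_u[s],
                                  _["mean_x"] = tr_x[s]);

  List out = List::create(
      _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["n_spikes"] = IntegerVector(n_spikes.begin(), n_spikes.end()),
      _["V_final"] = NumericVector(V.begin(), V.end()),
      _["traces"] = traces);
  if (return_stp) {
    out["stp_u"] = NumericVector(su.begin(), su.end());
    out["stp_x"] = NumericVector(sx.begin(), sx.end());
    out["stp_t_last"] = NumericVector(st_last.begin(), st_last.end());
  }
  return out;
}
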