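#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, causal single pass (a[0] must be 1).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] != 1.0) {
    for (int i = 0; i <= nz; ++i) { bb[i] /= aa[0]; if (i) aa[i] /= aa[0]; }
    aa[0] = 1.0;
  }
  int n = x.size();
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}

// Clock-driven simulation of the 2-layer LIF network with compound
// binary-device synapses and probabilistic STDP. Uses R's RNG (unif_rand /
// norm_rand) so that a pure-R re-implementation drawing runif()/rnorm() in
// the same order is bit-identical.
//
// drive: T x n_in matrix of rectified channel amplitudes.
// dev_state: n_dev x (n_in*n_out) 0/1 matrix (1 = LRS); synapse s = i + j*n_in.
// dev_g: matching conductance matrix (S).
// [[Rcpp::export]]
List run_network_cpp(NumericMatrix drive, double dt, double t0,
                     double thr1, double tleak1, double tref1, double input_gain,
                     double thr2, double tleak2, double tref2, double syn_gain,
                     double inhibition_s,
                     IntegerMatrix dev_state, NumericMatrix dev_g,
                     double g_min, double g_max,
                     double p_set, double p_reset, double t_ltp,
                     double median_lrs_ohm, double sdlog_lrs,
                     double median_hrs_ohm, double sdlog_hrs,
                     double e_set, double e_reset,
                     double v_read, double t_read,
                     bool learning, int snapshot_every) {
  const int T = drive.nrow();
  const int n_in = drive.ncol();
  const int n_syn = dev_state.ncol();
  const int n_dev = dev_state.nrow();
  const int n_out = n_syn / n_in;
  const double decay1 = std::exp(-dt / tleak1);
  const double decay2 = std::exp(-dt / tleak2);
  const double v2t = v_read * v_read * t_read;
  const double log_mlrs = std::log(median_lrs_ohm);
  const double log_mhrs = std::log(median_hrs_ohm);
  const double wspan = g_max - g_min;

  RNGScope scope;

  // per-synapse conductance sums (device order ascending, matching colSums)
  std::vector<double> g_sum(n_syn, 0.0);
  for (int s = 0; s < n_syn; ++s) {
    double acc = 0.0;
    for (int d = 0; d < n_dev; ++d) acc += dev_g(d, s);
    g_sum[s] = acc;
  }

  std::vector<double> integ1(n_in, 0.0), integ2(n_out, 0.0);
  std::vector<double> ref1(n_in, R_NegInf), ref2(n_out, R_NegInf);
  std::vector<double> inh2(n_out, R_NegInf);
  std::vector<double> last_pre(n_in, R_NegInf);

  std::vector<double> in_t, out_t;
  std::vector<int> in_id, out_id;
  std::vector<int> fired_now(n_in);

  double n_read = 0, n_set = 0, n_reset = 0;
  double e_read_j = 0, e_set_j = 0, e_reset_j = 0;

  List snaps;
  std::vector<double> snap_times;

  std::vector<double> drive2(n_out);

  for (int step = 0; step < T; ++step) {
    const double t = t0 + step * dt;

    // ---- layer 1 ----
    int n_fired = 0;
    for (int i = 0; i < n_in; ++i) {
      if (t <= ref1[i]) continue;           // absolute refractory: frozen
      double d1 = input_gain * drive(step, i) * dt;
      integ1[i] = integ1[i] * decay1 + d1;
      if (integ1[i] >= thr1) {
        integ1[i] = 0.0;
        ref1[i] = t + tref1;
        last_pre[i] = t;
        fired_now[n_fired++] = i;
        in_t.push_back(t);
        in_id.push_back(i + 1);
      }
    }

    // ---- synaptic delivery + read accounting ----
    std::fill(drive2.begin(), drive2.end(), 0.0);
    for (int k = 0; k < n_fired; ++k) {
      const int i = fired_now[k];
      for (int j = 0; j < n_out; ++j) {
        const int s = i + j * n_in;
        n_read += n_dev;                    // one read event per device
        e_read_j += v2t * g_sum[s];         // E = V^2/R * t summed over devices
        double w = (g_sum[s] - g_min) / wspan;
        if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;
        drive2[j] += w * syn_gain;
      }
    }

    // ---- layer 2 ----
    int winner = -1;
    double best = R_NegInf;
    for (int j = 0; j < n_out; ++j) {
      double gate = ref2[j] > inh2[j] ? ref2[j] : inh2[j];
      if (t <= gate) continue;              // refractory or inhibited: frozen
      integ2[j] = integ2[j] * decay2 + drive2[j];
      if (integ2[j] >= thr2 && integ2[j] > best) {
        best = integ2[j];
        winner = j;                         // argmax, ties keep lowest id
      }
    }

    if (winner >= 0) {
      out_t.push_back(t);
      out_id.push_back(winner + 1);
      integ2[winner] = 0.0;
      ref2[winner] = t + tref2;
      for (int j = 0; j < n_out; ++j) {
        if (j == winner) continue;
        integ2[j] = 0.0;                    // winner-take-all reset
        inh2[j] = t + inhibition_s;
      }

      if (learning) {
        // simplified probabilistic STDP for the winner's afferents
        for (int i = 0; i < n_in; ++i) {
          const int s = i + winner * n_in;
          const bool ltp = (t - last_pre[i]) < t_ltp;  // never-spiked => LTD
          if (ltp) {
            for (int d = 0; d < n_dev; ++d) {
              if (dev_state(d, s) == 0 && unif_rand() < p_set) {
                dev_state(d, s) = 1;
                double g_new = std::exp(-(log_mlrs + sdlog_lrs * norm_rand()));
                g_sum[s] += g_new - dev_g(d, s);
                dev_g(d, s) = g_new;
                n_set += 1; e_set_j += e_set;
              }
            }
          } else {
            for (int d = 0; d < n_dev; ++d) {
              if (dev_state(d, s) == 1 && unif_rand() < p_reset) {
                dev_state(d, s) = 0;
                double g_new = std::exp(-(log_mhrs + sdlog_hrs * norm_rand()));
                g_sum[s] += g_new - dev_g(d, s);
                dev_g(d, s) = g_new;
                n_reset += 1; e_reset_j += e_reset;
              }
            }
          }
        }
      }
    }

    if (snapshot_every > 0 && (step + 1) % snapshot_every == 0) {
      NumericMatrix w(n_in, n_out);
      for (int j = 0; j < n_out; ++j)
        for (int i = 0; i < n_in; ++i) {
          double ww = (g_sum[i + j * n_in] - g_min) / wspan;
          w(i, j) = ww < 0 ? 0 : (ww > 1 ? 1 : ww);
        }
      snaps.push_back(w);
      snap_times.push_back(t + dt);
    }
  }

  return List::create(
    _["in_time"] = in_t, _["in_id"] = in_id,
    _["out_time"] = out_t, _["out_id"] = out_id,
    _["dev_state"] = dev_state, _["dev_g"] = dev_g,
    _["g_sum"] = g_sum,
    _["n_read"] = n_read, _["n_set"] = n_set, _["n_reset"] = n_reset,
    _["e_read_j"] = e_read_j, _["e_set_j"] = e_set_j,
    _["e_reset_j"] = e_reset_j,
    _["snapshots"] = snaps, _["snapshot_times"] = snap_times);
}
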