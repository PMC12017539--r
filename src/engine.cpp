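#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inverse-transform Poisson sampler on R's uniform stream; exact for the
// small per-step means used here, falls back to R's rpois for large means.
static inline int rpois_small(double lambda, double exp_neg_lambda) {
  if (lambda <= 0.0) return 0;
  if (lambda > 10.0) return (int) R::rpois(lambda);
  double u = unif_rand();
  double p = exp_neg_lambda, cdf = p;
  int k = 0;
  while (u > cdf && k < 1000) {
    ++k;
    p *= lambda / k;
    cdf += p;
  }
  return k;
}

// Time-stepped integration of the full column. Per step: (1) update the
// external-current vector from epoch on/offsets, (2) draw per-neuron binned
// background Poisson events, (3) deliver last step's spikes through the
// receptor-specific adjacency, (4) advance gating (exact decay for the
// linear channels, forward Euler for the saturating NMDA fraction),
// (5) compute currents and advance membranes with forward Euler, detecting
// spikes, resetting and starting refractoriness.
// [[Rcpp::export]]
List cpp_run_column(int n_steps, double dt,
                    NumericVector v_rest, NumericVector v_th,
                    NumericVector c_m, NumericVector g_l,
                    NumericVector tau_ref, NumericVector lambda_bg,
                    IntegerVector ampa_ptr, IntegerVector ampa_post,
                    NumericVector ampa_w,
                    IntegerVector nmda_ptr, IntegerVector nmda_post,
                    NumericVector nmda_w,
                    IntegerVector gaba_ptr, IntegerVector gaba_post,
                    NumericVector gaba_w,
                    double tau_ampa, double tau_nmda_decay,
                    double tau_nmda_rise, double alpha, double tau_gaba,
                    double mg, double g_ampa, double g_nmda, double g_gaba,
                    double v_e,
                    NumericVector ep_on, NumericVector ep_off,
                    NumericVector ep_amp, IntegerVector ep_ptr,
                    IntegerVector ep_ids,
                    IntegerVector record_ids, int record_every,
                    int delay_steps) {
  const int n = v_rest.size();
  std::vector<double> V(n), refrac(n, 0.0), iext(n, 0.0);
  std::vector<double> s_bg(n, 0.0), s_ampa(n, 0.0), s_gaba(n, 0.0);
  std::vector<double> s_nmda(n, 0.0), x_nmda(n, 0.0);
  for (int i = 0; i < n; ++i) V[i] = v_rest[i];

  const double d_ampa = std::exp(-dt / tau_ampa);
  const double d_gaba = std::exp(-dt / tau_gaba);
  const double d_xr = std::exp(-dt / tau_nmda_rise);
  std::vector<double> exp_neg_lambda(n);
  for (int i = 0; i < n; ++i) exp_neg_lambda[i] = std::exp(-lambda_bg[i]);

  const int n_ep = ep_on.size();
  std::vector<int> ep_on_step(n_ep), ep_off_step(n_ep);
  for (int e = 0; e < n_ep; ++e) {
    ep_on_step[e] = (int) std::lround(ep_on[e] / dt);
    double off = ep_off[e] / dt;
    ep_off_step[e] = off > n_steps ? n_steps + 1 : (int) std::lround(off);
  }

  // ring buffer of spike lists: spikes detected at step t are delivered at
  // step t + delay_steps (a fixed transmission latency in wall-clock terms,
  // one step at the default 0.1 ms resolution)
  if (delay_steps < 1) delay_steps = 1;
  std::vector< std::vector<int> > ring(delay_steps);
  std::vector<int> spike_id;
  std::vector<double> spike_t;

  const int n_rec = record_ids.size();
  int n_samples = (record_every > 0 && n_rec > 0) ? n_steps / record_every : 0;
  NumericMatrix vrec(n_samples, n_rec);
  NumericVector vrec_t(n_samples);
  int sample_row = 0;

  for (int t = 0; t < n_steps; ++t) {
    // (1) external DC epochs
    for (int e = 0; e < n_ep; ++e) {
      if (ep_on_step[e] == t)
        for (int k = ep_ptr[e]; k < ep_ptr[e + 1]; ++k)
          iext[ep_ids[k]] += ep_amp[e];
      if (ep_off_step[e] == t)
        for (int k = ep_ptr[e]; k < ep_ptr[e + 1]; ++k)
          iext[ep_ids[k]] -= ep_amp[e];
    }
    // (2) background Poisson deliveries (unit weight per event)
    for (int i = 0; i < n; ++i) {
      int k = rpois_small(lambda_bg[i], exp_neg_lambda[i]);
      if (k > 0) s_bg[i] += k;
    }
    // (3) deliver spikes whose latency has elapsed
    std::vector<int>& due = ring[t % delay_steps];
    for (size_t si = 0; si < due.size(); ++si) {
      int j = due[si];
      for (int k = ampa_ptr[j]; k < ampa_ptr[j + 1]; ++k)
        s_ampa[ampa_post[k]] += ampa_w[k];
      for (int k = nmda_ptr[j]; k < nmda_ptr[j + 1]; ++k)
        x_nmda[nmda_post[k]] += nmda_w[k];
      for (int k = gaba_ptr[j]; k < gaba_ptr[j + 1]; ++k)
        s_gaba[gaba_post[k]] += gaba_w[k];
    }
    due.clear();
    // (4) gating dynamics, (5) currents and membrane
    double tnow = (t + 1) * dt;
    for (int i = 0; i < n; ++i) {
      s_bg[i] *= d_ampa;
      s_ampa[i] *= d_ampa;
      s_gaba[i] *= d_gaba;
      double s = s_nmda[i];
      s += dt * (-s / tau_nmda_decay + alpha * x_nmda[i] * (1.0 - s));
      if (s > 1.0 || s < 0.0)
        stop("NMDA gating left [0,1] for neuron %d at step %d (dt too large)",
             i + 1, t + 1);
      s_nmda[i] = s;
      x_nmda[i] *= d_xr;

      if (refrac[i] > 0.0) {
        V[i] = v_rest[i];
        refrac[i] -= dt;
        if (refrac[i] < 0.0) refrac[i] = 0.0;
        continue;
      }
      double v = V[i];
      double drive_e = v_e - v;
      double f_mg = 1.0 / (1.0 + mg * std::exp(-0.062 * v) / 3.57);
      double isyn = iext[i] +
        g_ampa * (s_bg[i] + s_ampa[i]) * drive_e +
        g_nmda * f_mg * s_nmda[i] * drive_e +
        g_gaba * s_gaba[i] * (v_rest[i] - v);
      v += dt / c_m[i] * (-g_l[i] * (v - v_rest[i]) + isyn);
      if (!std::isfinite(v) || std::fabs(v) > 500.0)
        stop("membrane potential diverged for neuron %d at step %d",
             i + 1, t + 1);
      if (v >= v_th[i]) {
        spike_id.push_back(i + 1);
        spike_t.push_back(tnow);
        ring[t % delay_steps].push_back(i);
        v = v_rest[i];
        refrac[i] = tau_ref[i];
      }
      V[i] = v;
    }
    // voltage recording (decimated)
    if (n_samples > 0 && (t + 1) % record_every == 0 && sample_row < n_samples) {
      for (int r = 0; r < n_rec; ++r)
        vrec(sample_row, r) = V[record_ids[r]];
      vrec_t[sample_row] = tnow;
      ++sample_row;
    }
  }

  return List::create(
    _["spike_id"] = wrap(spike_id),
    _["spike_t"] = wrap(spike_t),
    _["voltage"] = vrec,
    _["voltage_t"] = vrec_t,
    _["V_final"] = wrap(V));
}
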