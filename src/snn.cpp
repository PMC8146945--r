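#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Step Forward encoding: fixed threshold, moving baseline. One spike and one
// baseline step per sample at most.
// [[Rcpp::export]]
List sf_encode_core(NumericMatrix x, NumericVector thr, NumericVector b0) {
  int n_ch = x.nrow(), n = x.ncol();
  IntegerMatrix spikes(n_ch, n);
  NumericVector b_final(n_ch);
  for (int c = 0; c < n_ch; ++c) {
    double B = b0[c], th = thr[c];
    for (int i = 0; i < n; ++i) {
      double d = x(c, i) - B;
      if (d > th)       { spikes(c, i) = 1;  B += th; }
      else if (-d > th) { spikes(c, i) = -1; B -= th; }
    }
    b_final[c] = B;
  }
  return List::create(_["spikes"] = spikes, _["baseline_final"] = b_final);
}

// RMSE between a signal and its SF-decoded baseline trajectory, for every
// candidate threshold; used by the threshold-optimization grid search.
// [[Rcpp::export]]
NumericVector sf_grid_rmse(NumericVector x, NumericVector grid, double b0) {
  int n = x.size(), g = grid.size();
  NumericVector rmse(g);
  for (int k = 0; k < g; ++k) {
    double th = grid[k], B = b0, acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = x[i] - B;
      if (d > th) B += th; else if (-d > th) B -= th;
      double e = x[i] - B;
      acc += e * e;
    }
    rmse[k] = std::sqrt(acc / n);
  }
  return rmse;
}

// Discrete-time leaky integrate-and-fire reservoir with optional
// spike-timing-dependent plasticity (nearest-spike rule, strictly earlier
// spikes only; simultaneous spikes cause no update).
//
// Per step t (0-based, within pass p; global step g = p*T + t):
//   1. non-refractory potentials leak: v *= exp(-1/tau_m)
//   2. spikes fired at g-1 deliver their weights to targets
//   3. input raster column t injects sign * v_thr * k_in at mapped neurons
//   4. neurons with v >= v_thr fire; STDP updates use last-fire times from
//      strictly earlier steps; then v -> v_reset and refractory starts
// Refractory semantics: a neuron that fired at g cannot fire again before
// g + refrac; while refractory it ignores all input and holds v_reset.
// [[Rcpp::export]]
List lif_stdp_core(int n_neurons,
                   IntegerVector edge_src, IntegerVector edge_tgt,
                   NumericVector edge_w, IntegerVector edge_sign,
                   IntegerMatrix raster, IntegerVector input_map,
                   double tau_m, double v_thr, double v_reset,
                   int refrac, double k_in,
                   bool learn, double a_plus, double a_minus,
                   double tau_plus, double tau_minus,
                   double w_min, double w_max,
                   int passes, bool record_v, NumericVector v0) {
  int n_edges = edge_src.size();
  int n_ch = raster.nrow(), T = raster.ncol();
  std::vector<double> w(edge_w.begin(), edge_w.end());

  // adjacency: outgoing (CSR by source) and incoming (by target) edge ids
  std::vector<int> out_cnt(n_neurons, 0), in_cnt(n_neurons, 0);
  for (int e = 0; e < n_edges; ++e) {
    out_cnt[edge_src[e]]++; in_cnt[edge_tgt[e]]++;
  }
  std::vector<int> out_ptr(n_neurons + 1, 0), in_ptr(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) {
    out_ptr[i + 1] = out_ptr[i] + out_cnt[i];
    in_ptr[i + 1] = in_ptr[i] + in_cnt[i];
  }
  std::vector<int> out_e(n_edges), in_e(n_edges);
  {
    std::vector<int> oi(out_ptr.begin(), out_ptr.end() - 1),
                     ii(in_ptr.begin(), in_ptr.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      out_e[oi[edge_src[e]]++] = e;
      in_e[ii[edge_tgt[e]]++] = e;
    }
  }

  std::vector<double> v(n_neurons, 0.0);
  for (int i = 0; i < n_neurons && i < v0.size(); ++i) v[i] = v0[i];
  std::vector<long> last_fire(n_neurons, -1), next_ok(n_neurons, 0);
  std::vector<int> prev_fired, fired_now;
  std::vector<int> out_step, out_neuron;
  double decay = std::exp(-1.0 / tau_m);
  long total_steps = (long)T * passes;
  NumericMatrix vtrace(record_v ? n_neurons : 1,
                       record_v ? (int)total_steps : 1);

  // potentiation grows, depression shrinks, the magnitude; the sign is a
  // fixed property of the edge (excitatory/inhibitory source neuron)
  auto apply_dw = [&](int e, double dmag) {
    double mag = std::fabs(w[e]) + dmag;
    if (mag < 0) mag = 0;
    if (edge_sign[e] < 0) {
      double neww = -mag;
      w[e] = std::max(neww, w_min);
    } else {
      w[e] = std::min(mag, w_max);
    }
  };

  for (int p = 0; p < passes; ++p) {
    for (int t = 0; t < T; ++t) {
      long g = (long)p * T + t;
      // 1. leak
      for (int i = 0; i < n_neurons; ++i)
        if (g >= next_ok[i]) v[i] *= decay; else v[i] = v_reset;
      // 2. recurrent delivery from previous step
      for (size_t fi = 0; fi < prev_fired.size(); ++fi) {
        int f = prev_fired[fi];
        for (int k = out_ptr[f]; k < out_ptr[f + 1]; ++k) {
          int e = out_e[k], j = edge_tgt[e];
          if (g >= next_ok[j]) v[j] += w[e];
        }
      }
      // 3. input injection
      for (int c = 0; c < n_ch; ++c) {
        int s = raster(c, t);
        if (s != 0) {
          int j = input_map[c];
          if (g >= next_ok[j]) v[j] += s * v_thr * k_in;
        }
      }
      // 4. fire + STDP
      fired_now.clear();
      for (int i = 0; i < n_neurons; ++i)
        if (g >= next_ok[i] && v[i] >= v_thr) fired_now.push_back(i);
      if (learn) {
        for (size_t fi = 0; fi < fired_now.size(); ++fi) {
          int j = fired_now[fi];
          for (int k = in_ptr[j]; k < in_ptr[j + 1]; ++k) {
            int e = in_e[k], i = edge_src[e];
            long lf = last_fire[i];
            if (lf >= 0 && lf < g)
              apply_dw(e, a_plus * std::exp(-(double)(g - lf) / tau_plus));
          }
          for (int k = out_ptr[j]; k < out_ptr[j + 1]; ++k) {
            int e = out_e[k], tgt = edge_tgt[e];
            long lf = last_fire[tgt];
            if (lf >= 0 && lf < g)
              apply_dw(e, -a_minus * std::exp(-(double)(g - lf) / tau_minus));
          }
        }
      }
      for (size_t fi = 0; fi < fired_now.size(); ++fi) {
        int i = fired_now[fi];
        last_fire[i] = g;
        v[i] = v_reset;
        next_ok[i] = g + refrac;
        out_step.push_back((int)g);
        out_neuron.push_back(i);
      }
      if (record_v)
        for (int i = 0; i < n_neurons; ++i) vtrace(i, (int)g) = v[i];
      prev_fired = fired_now;
    }
  }

  List res = List::create(
    _["fired_step"] = IntegerVector(out_step.begin(), out_step.end()),
    _["fired_neuron"] = IntegerVector(out_neuron.begin(), out_neuron.end()),
    _["w"] = NumericVector(w.begin(), w.end()));
  if (record_v) res["potentials"] = vtrace;
  return res;
}
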