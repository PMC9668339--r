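#include <Rcpp.h>
using namespace Rcpp;

// Sequential (autoregressive) Poisson spike generation with spike-history and
// directed unit-to-unit coupling kernels. eta0 holds the task-driven log rate
// per bin and unit (intercept + tuning + event filters + LFP phase terms);
// history and coupling contributions are accumulated causally as counts are
// drawn, so fitted causal filters have a well-defined ground truth.
//
// eta0:   T x U log-rate matrix (task contribution)
// hist:   Lh x U spike-history kernels (column of zeros = no history term)
// edge_s, edge_r: 0-based sender / receiver unit indices per coupling edge
// edge_k: Lk x E coupling kernels (one column per edge)
// max_rate: cap on the per-bin Poisson mean (spikes per bin)
// [[Rcpp::export]]
IntegerMatrix gen_spikes_seq(NumericMatrix eta0, NumericMatrix hist,
                             IntegerVector edge_s, IntegerVector edge_r,
                             NumericMatrix edge_k, double max_rate) {
  const int T = eta0.nrow(), U = eta0.ncol();
  const int Lh = hist.nrow();
  const int E = edge_s.size();
  const int Lk = edge_k.nrow();
  IntegerMatrix y(T, U);
  const double log_cap = std::log(max_rate);
  for (int t = 0; t < T; ++t) {
    for (int u = 0; u < U; ++u) {
      double eta = eta0(t, u);
      for (int l = 1; l <= Lh && l <= t; ++l) {
        double h = hist(l - 1, u);
        if (h != 0.0) eta += h * y(t - l, u);
      }
      for (int e = 0; e < E; ++e) {
        if (edge_r[e] != u) continue;
        const int s = edge_s[e];
        for (int l = 1; l <= Lk && l <= t; ++l) {
          double k = edge_k(l - 1, e);
          if (k != 0.0) eta += k * y(t - l, s);
        }
      }
      if (eta > log_cap) eta = log_cap;
      y(t, u) = R::rpois(std::exp(eta));
    }
  }
  return y;
}
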