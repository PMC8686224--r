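// Stochastic gradient layout of the multigraph by weighted fuzzy
// cross-entropy, with negative sampling. Single-threaded and fully
// deterministic: every edge owns an independent counter-based RNG stream
// keyed by its endpoints, so removing or re-weighting one edge never
// perturbs the random draws of another.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double clip4(double v) {
  return v > 4.0 ? 4.0 : (v < -4.0 ? -4.0 : v);
}

// [[Rcpp::export]]
List optimize_layout_cpp(NumericMatrix init,
                         IntegerVector head,  // 1-based
                         IntegerVector tail,  // 1-based
                         NumericVector epochs_per_sample,
                         NumericVector edge_weight,
                         double a, double b, double gamma,
                         double alpha0, int n_epochs,
                         double negative_sample_rate,
                         double seed,
                         bool weight_repulsion,
                         IntegerVector snapshot_epochs) {
  const int n_vertices = init.nrow();
  const int d = init.ncol();
  const int n_edges = head.size();

  NumericMatrix emb = clone(init);
  double *x = REAL(emb);

  std::vector<uint64_t> rng(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    uint64_t s = (uint64_t)seed;
    s ^= 0x243F6A8885A308D3ULL * (uint64_t)(head[e]);
    s ^= 0xB7E151628AED2A6BULL * ((uint64_t)(tail[e]) << 17);
    splitmix64(s);
    splitmix64(s);
    rng[e] = s;
  }

  std::vector<double> next_sample(n_edges), next_neg(n_edges), eps_neg(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    next_sample[e] = epochs_per_sample[e];
    eps_neg[e] = epochs_per_sample[e] / negative_sample_rate;
    next_neg[e] = eps_neg[e];
  }

  std::vector<int> snaps(snapshot_epochs.begin(), snapshot_epochs.end());
  List snapshots(snaps.size());
  long long n_skipped = 0;
  std::vector<double> grad(d);

  for (int n = 0; n < n_epochs; ++n) {
    const double alpha = alpha0 * (1.0 - (double)n / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (next_sample[e] > n) continue;
      const int h = head[e] - 1;
      const int t = tail[e] - 1;
      const double w = edge_weight[e];
      double *xh = x + h;
      double *xt = x + t;

      double rd2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = xh[(size_t)k * n_vertices] - xt[(size_t)k * n_vertices];
        rd2 += diff * diff;
      }
      double coeff = 0.0;
      if (rd2 > 0.0) {
        const double pd2b = std::pow(rd2, b);
        coeff = (-2.0 * a * b * pd2b / rd2) / (a * pd2b + 1.0);
      }
      bool ok = true;
      for (int k = 0; k < d; ++k) {
        const size_t off = (size_t)k * n_vertices;
        const double diff = xh[off] - xt[off];
        const double val = clip4(coeff * diff) * alpha * w;
        grad[k] = val;
        if (!std::isfinite(val)) ok = false;
      }
      if (ok) {
        for (int k = 0; k < d; ++k) {
          const size_t off = (size_t)k * n_vertices;
          xh[off] += grad[k];
          xt[off] -= grad[k];
        }
      } else {
        ++n_skipped;
      }
      next_sample[e] += epochs_per_sample[e];

      const int n_neg = (int)((n - next_neg[e]) / eps_neg[e]);
      const double wr = weight_repulsion ? w : 1.0;
      for (int p = 0; p < n_neg; ++p) {
        const int kidx = (int)(splitmix64(rng[e]) % (uint64_t)n_vertices);
        if (kidx == h) continue;
        double *xk = x + kidx;
        double rk2 = 0.0;
        for (int k = 0; k < d; ++k) {
          const size_t off = (size_t)k * n_vertices;
          const double diff = xh[off] - xk[off];
          rk2 += diff * diff;
        }
        double rcoeff = 0.0;
        if (rk2 > 0.0) {
          rcoeff = (2.0 * gamma * b) /
                   ((0.001 + rk2) * (a * std::pow(rk2, b) + 1.0));
        }
        bool rok = true;
        for (int k = 0; k < d; ++k) {
          const size_t off = (size_t)k * n_vertices;
          const double diff = xh[off] - xk[off];
          double val;
          if (rcoeff > 0.0) {
            val = clip4(rcoeff * diff) * alpha * wr;
          } else {
            val = 4.0 * alpha * wr;  // coincident points: push apart hard
          }
          grad[k] = val;
          if (!std::isfinite(val)) rok = false;
        }
        if (rok) {
          for (int k = 0; k < d; ++k) {
            xh[(size_t)k * n_vertices] += grad[k];
          }
        } else {
          ++n_skipped;
        }
      }
      next_neg[e] += n_neg * eps_neg[e];
    }
    for (size_t s = 0; s < snaps.size(); ++s) {
      if (snaps[s] == n + 1) snapshots[s] = clone(emb);
    }
    if (n % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["embedding"] = emb,
                      _["snapshots"] = snapshots,
                      _["n_skipped"] = (double)n_skipped);
}
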