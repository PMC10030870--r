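#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Short-range Gaussian repulsion between layout points:
//   V = a_N * sum_{i<j, r_ij <= cutoff} exp(-r_ij^2 / (4 r0^2))
// with analytic gradient dV/dx_i. Two evaluation paths: brute-force O(N^2)
// and a cell list with grid spacing = cutoff (rebuilt on every call), which
// visits only pairs in adjacent cells and is exact for the truncated
// potential.

static inline void accum_pair(const NumericMatrix& X, int i, int j, int d,
                              double aN, double inv4r0sq, double cutsq,
                              double& energy, NumericMatrix* grad) {
  double r2 = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = X(i, c) - X(j, c);
    r2 += diff * diff;
  }
  if (r2 > cutsq) return;
  double e = aN * std::exp(-r2 * inv4r0sq);
  energy += e;
  if (grad) {
    // dV/dx_i = -e * (x_i - x_j) / (2 r0^2); pairwise equal and opposite
    double coef = -e * 2.0 * inv4r0sq;
    for (int c = 0; c < d; ++c) {
      double diff = X(i, c) - X(j, c);
      (*grad)(i, c) += coef * diff;
      (*grad)(j, c) -= coef * diff;
    }
  }
}

// [[Rcpp::export]]
List repulsion_terms_cpp(NumericMatrix X, double aN, double r0, double cutoff,
                         bool cell_list, bool want_grad) {
  const int n = X.nrow(), d = X.ncol();
  const double inv4r0sq = 1.0 / (4.0 * r0 * r0);
  const double cutsq = cutoff * cutoff;
  double energy = 0.0;
  NumericMatrix grad;
  NumericMatrix* gp = nullptr;
  if (want_grad) {
    grad = NumericMatrix(n, d);
    gp = &grad;
  }

  if (aN > 0.0 && n > 1) {
    if (!cell_list) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          accum_pair(X, i, j, d, aN, inv4r0sq, cutsq, energy, gp);
    } else {
      // integer cell coordinates, packed into a 64-bit key (21 bits/axis)
      std::vector<int64_t> cx(n), cy(n), cz(n);
      double mn[3] = {0, 0, 0};
      for (int c = 0; c < d; ++c) {
        double m = X(0, c);
        for (int i = 1; i < n; ++i) m = std::min(m, X(i, c));
        mn[c] = m;
      }
      auto cellof = [&](int i, int c) -> int64_t {
        return (int64_t) std::floor((X(i, c) - mn[c]) / cutoff);
      };
      std::unordered_map<int64_t, std::vector<int>> bins;
      bins.reserve(n * 2);
      auto key = [&](int64_t a, int64_t b, int64_t c) -> int64_t {
        return ((a & 0x1FFFFF) << 42) | ((b & 0x1FFFFF) << 21) | (c & 0x1FFFFF);
      };
      for (int i = 0; i < n; ++i) {
        cx[i] = cellof(i, 0);
        cy[i] = cellof(i, 1);
        cz[i] = (d == 3) ? cellof(i, 2) : 0;
        bins[key(cx[i], cy[i], cz[i])].push_back(i);
      }
      const int zlo = (d == 3) ? -1 : 0, zhi = (d == 3) ? 1 : 0;
      for (auto& kv : bins) {
        const std::vector<int>& here = kv.second;
        int64_t ax = cx[here[0]], ay = cy[here[0]], az = cz[here[0]];
        // same-cell pairs
        for (size_t s = 0; s < here.size(); ++s)
          for (size_t t = s + 1; t < here.size(); ++t)
            accum_pair(X, here[s], here[t], d, aN, inv4r0sq, cutsq, energy, gp);
        // half of the neighbor offsets, to count each cell pair once
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = zlo; oz <= zhi; ++oz) {
              if (ox < 0) continue;
              if (ox == 0 && oy < 0) continue;
              if (ox == 0 && oy == 0 && oz <= 0) continue;
              auto it = bins.find(key(ax + ox, ay + oy, az + oz));
              if (it == bins.end()) continue;
              for (int i : here)
                for (int j : it->second)
                  accum_pair(X, i, j, d, aN, inv4r0sq, cutsq, energy, gp);
            }
      }
    }
  }

  if (want_grad) return List::create(_["energy"] = energy, _["gradient"] = grad);
  return List::create(_["energy"] = energy);
}
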