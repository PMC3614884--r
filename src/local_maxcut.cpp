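#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Self-contained xorshift64* generator: sweep orders must be reproducible
// from a seed across platforms and standard-library versions, which rules
// out std::shuffle / R's RNG inside the hot loop.
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t xs_next(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

// unbiased draw in [0, n) by rejection
static inline int xs_below(uint64_t &s, int n) {
  uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
  uint64_t x;
  do {
    x = xs_next(s);
  } while (x >= lim);
  return (int)(x % (uint64_t)n);
}

// Drive a bipartition to a local max-cut by repeated asynchronous sweeps.
// Graph in compressed sparse column form (symmetric, so CSC == CSR).
// side0: 0/1 assignment per vertex. A vertex moves when its imbalance
// h(v) = sum_{u same side} w(u,v) - sum_{u other side} w(u,v) drops
// below -eps; each such flip lowers the cut objective by 2|h(v)|.
// [[Rcpp::export]]
List local_maxcut_core(IntegerVector ptr, IntegerVector idx, NumericVector val,
                       IntegerVector side0, double eps, int max_sweeps,
                       double seed, bool trace) {
  const int n = side0.size();
  std::vector<int> side(side0.begin(), side0.end());

  // h(v) = sigma_v * sum_u w(u,v) sigma_u with sigma = +1 (side 0) / -1 (side 1)
  std::vector<double> h(n, 0.0);
  for (int v = 0; v < n; ++v) {
    double acc = 0.0;
    for (int j = ptr[v]; j < ptr[v + 1]; ++j)
      acc += val[j] * (side[idx[j]] ? -1.0 : 1.0);
    h[v] = (side[v] ? -1.0 : 1.0) * acc;
  }

  uint64_t seed_state = (uint64_t)seed;
  uint64_t rng = splitmix64(seed_state);
  if (rng == 0) rng = 0x9e3779b97f4a7c15ULL;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<int> moves;
  int sweeps = 0;
  double total_moves = 0;
  bool converged = false;

  while (sweeps < max_sweeps) {
    ++sweeps;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = xs_below(rng, i + 1);
      std::swap(order[i], order[j]);
    }
    int moved = 0;
    for (int k = 0; k < n; ++k) {
      int v = order[k];
      if (h[v] < -eps) {
        double sv_old = side[v] ? -1.0 : 1.0;
        side[v] = 1 - side[v];
        for (int j = ptr[v]; j < ptr[v + 1]; ++j) {
          int u = idx[j];
          h[u] -= 2.0 * val[j] * (side[u] ? -1.0 : 1.0) * sv_old;
        }
        h[v] = -h[v];
        ++moved;
        total_moves += 1;
        if (trace) moves.push_back(v + 1);
      }
    }
    if (moved == 0) {
      converged = true;
      break;
    }
  }

  return List::create(_["side"] = IntegerVector(side.begin(), side.end()),
                      _["sweeps"] = sweeps, _["moves"] = total_moves,
                      _["converged"] = converged,
                      _["trace"] = IntegerVector(moves.begin(), moves.end()));
}
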