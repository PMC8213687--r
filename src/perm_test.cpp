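#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// type-7 quantile on a sorted vector: h = level*(m-1), linear interpolation
// between the bracketing order statistics.
static inline double q_type7(const std::vector<double>& v, double level) {
  const int m = (int)v.size();
  if (m == 1) return v[0];
  double h = level * (m - 1);
  int lo = (int)std::floor(h);
  if (lo >= m - 1) return v[m - 1];
  return v[lo] + (h - lo) * (v[lo + 1] - v[lo]);
}

// splitmix64: seed expansion for the per-gene counter-based scheme
static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256** — small, fast, deterministic across platforms
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // unbiased bounded integer in [0, n)
  uint32_t bounded(uint32_t n) {
    uint64_t threshold = (UINT64_MAX - n + 1) % n;
    for (;;) {
      uint64_t r = next();
      if (r >= threshold) return (uint32_t)(r % n);
    }
  }
};

static void quantiles_of_split(const std::vector<double>& pool,
                               const std::vector<int>& in1,
                               int n1, const NumericVector& levels,
                               std::vector<double>& g1,
                               std::vector<double>& g2,
                               std::vector<double>& y) {
  const int n = (int)pool.size();
  g1.clear(); g2.clear();
  for (int i = 0; i < n; ++i) {
    if (in1[i]) g1.push_back(pool[i]); else g2.push_back(pool[i]);
  }
  std::sort(g1.begin(), g1.end());
  std::sort(g2.begin(), g2.end());
  for (int l = 0; l < levels.size(); ++l)
    y[l] = std::fabs(q_type7(g1, levels[l]) - q_type7(g2, levels[l]));
}

// [[Rcpp::export]]
List perm_quantile_test_cpp(NumericVector pooled, int n1, NumericVector levels,
                            std::string engine, double n_perm,
                            double seed, double counter) {
  const int n = pooled.size();
  const int n2 = n - n1;
  const int L = levels.size();
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty");

  std::vector<double> pool(pooled.begin(), pooled.end());
  std::vector<double> g1, g2, y(L);
  g1.reserve(n); g2.reserve(n);

  // observed: first n1 entries of `pooled` are group 1
  std::vector<int> in1(n, 0);
  for (int i = 0; i < n1; ++i) in1[i] = 1;
  std::vector<double> y_obs(L), q1_obs(L), q2_obs(L);
  {
    std::vector<double> a(pool.begin(), pool.begin() + n1);
    std::vector<double> b(pool.begin() + n1, pool.end());
    std::sort(a.begin(), a.end());
    std::sort(b.begin(), b.end());
    for (int l = 0; l < L; ++l) {
      q1_obs[l] = q_type7(a, levels[l]);
      q2_obs[l] = q_type7(b, levels[l]);
      y_obs[l] = std::fabs(q1_obs[l] - q2_obs[l]);
    }
  }
  std::vector<double> thr(L);
  for (int l = 0; l < L; ++l) thr[l] = y_obs[l] - 1e-9 * (1.0 + y_obs[l]);

  std::vector<double> count_ge(L, 0.0);
  double total = 0.0;

  if (engine == "exact") {
    // lexicographic enumeration of all C(n, n1) label assignments
    std::vector<int> comb(n1);
    for (int i = 0; i < n1; ++i) comb[i] = i;
    for (;;) {
      std::fill(in1.begin(), in1.end(), 0);
      for (int i = 0; i < n1; ++i) in1[comb[i]] = 1;
      quantiles_of_split(pool, in1, n1, levels, g1, g2, y);
      for (int l = 0; l < L; ++l) if (y[l] >= thr[l]) count_ge[l] += 1.0;
      total += 1.0;
      // next combination
      int i = n1 - 1;
      while (i >= 0 && comb[i] == n2 + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < n1; ++j) comb[j] = comb[j - 1] + 1;
    }
  } else if (engine == "mc") {
    // counter-based per-gene stream: results independent of iteration order
    uint64_t mix = (uint64_t)seed;
    uint64_t s0 = splitmix64(mix) ^ (0x9E3779B97F4A7C15ULL * ((uint64_t)counter + 1));
    Xoshiro rng(s0);
    std::vector<double> work(pool);
    const int B = (int)n_perm;
    for (int b = 0; b < B; ++b) {
      // partial Fisher-Yates: first n1 slots become group 1
      for (int i = 0; i < n1; ++i) {
        int j = i + (int)rng.bounded((uint32_t)(n - i));
        std::swap(work[i], work[j]);
      }
      std::vector<double> a(work.begin(), work.begin() + n1);
      std::vector<double> bb(work.begin() + n1, work.end());
      std::sort(a.begin(), a.end());
      std::sort(bb.begin(), bb.end());
      for (int l = 0; l < L; ++l) {
        double yy = std::fabs(q_type7(a, levels[l]) - q_type7(bb, levels[l]));
        if (yy >= thr[l]) count_ge[l] += 1.0;
      }
    }
    total = (double)B;
  } else {
    stop("unknown engine: %s", engine.c_str());
  }

  return List::create(_["y_obs"] = y_obs, _["q1"] = q1_obs, _["q2"] = q2_obs,
                      _["count_ge"] = count_ge, _["total"] = total);
}
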