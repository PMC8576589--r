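// Random-walk corpus generation core. Each walk draws from its own
// xorshift stream seeded by (seed, start vertex, walk index), so the
// corpus is reproducible and independent of iteration order.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};
} // namespace

// adj_to / adj_pred: concatenated per-vertex adjacency (1-based vertex and
// predicate ids); adj_start: 0-based offset of each vertex's slice
// (length nv + 1). cum: per-entry cumulative sampling probabilities
// aligned with adj_to (empty => uniform). Returns a list of integer
// matrices [len x 2]: vertex ids and predicate ids along each walk.
// [[Rcpp::export(name = ".walk_corpus_cpp")]]
List walk_corpus_cpp(IntegerVector adj_to, IntegerVector adj_pred,
                     IntegerVector adj_start, NumericVector cum,
                     int num_walks, int walk_length, int seed) {
  const int nv = adj_start.size() - 1;
  const bool weighted = cum.size() > 0;
  List out(static_cast<R_xlen_t>(nv) * num_walks);
  std::vector<int> wv(walk_length), wp(walk_length);
  R_xlen_t k = 0;
  for (int vi = 1; vi <= nv; ++vi) {
    for (int wi = 1; wi <= num_walks; ++wi) {
      uint64_t ws = (static_cast<uint64_t>(seed < 0 ? -seed : seed) * 48271ULL
                     + static_cast<uint64_t>(vi) * 65537ULL
                     + static_cast<uint64_t>(wi) * 257ULL);
      XorShift64 rng(ws * 0x2545F4914F6CDD1DULL + 1ULL);
      int cur = vi;
      int len = 1;
      wv[0] = cur; wp[0] = 0;
      for (int step = 1; step < walk_length; ++step) {
        const int a = adj_start[cur - 1], b = adj_start[cur];
        const int m = b - a;
        if (m <= 0) break;
        int j;
        const double u = rng.unif();
        if (!weighted) {
          j = a + static_cast<int>(u * m);
          if (j >= b) j = b - 1;
        } else {
          // binary search in the vertex's cumulative slice
          int lo = a, hi = b - 1;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (cum[mid] < u) lo = mid + 1; else hi = mid;
          }
          j = lo;
        }
        cur = adj_to[j];
        wv[len] = cur;
        wp[len] = adj_pred[j];
        ++len;
      }
      IntegerMatrix w(len, 2);
      for (int i = 0; i < len; ++i) { w(i, 0) = wv[i]; w(i, 1) = wp[i]; }
      out[k++] = w;
    }
  }
  return out;
}
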