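// Skip-gram negative-sampling trainer for random-walk corpora.
// Single-threaded, deterministic given the seed. Follows the classic
// word2vec training scheme: for each (center, context) pair inside a
// dynamically shrunk window, one positive update and `negative` noise
// updates drawn from the unigram distribution raised to the 3/4 power.
#include <Rcpp.h>
#include <vector>
#include <cmath>
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
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// corpus: list of 0-based integer vectors over a vocabulary of size vocab.
// counts: token frequencies (length vocab), used for the noise distribution.
// Returns the input-layer matrix (vocab x dim).
// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(List corpus, int vocab, NumericVector counts,
                             int dim, int window, double alpha,
                             int negative, int epochs, int seed) {
  if (vocab < 1) stop("empty vocabulary");
  if (dim < 1) stop("dimension must be positive");
  const double alpha_min = alpha * 1e-4;

  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(vocab);
  double tot = 0.0;
  for (int i = 0; i < vocab; ++i) {
    tot += std::pow(std::max(counts[i], 1.0), 0.75);
    cum[i] = tot;
  }
  auto draw_noise = [&]() {
    double u = rng.unif() * tot;
    int lo = 0, hi = vocab - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  // total training tokens, for the linear learning-rate decay
  double total_tokens = 0.0;
  const int nseq = corpus.size();
  for (int s = 0; s < nseq; ++s)
    total_tokens += static_cast<double>(Rf_xlength(VECTOR_ELT(corpus, s)));
  total_tokens *= epochs;
  if (total_tokens <= 0) stop("empty corpus");

  std::vector<double> neu1e(dim);
  double trained = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nseq; ++s) {
      IntegerVector sent = corpus[s];
      const int n = sent.size();
      for (int pos = 0; pos < n; ++pos) {
        trained += 1.0;
        double lr = alpha * (1.0 - trained / (total_tokens + 1.0));
        if (lr < alpha_min) lr = alpha_min;
        const int center = sent[pos];
        const int b = rng.below(window);  // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          const int context = sent[cpos];
          double* v = &syn0[static_cast<size_t>(context) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              target = draw_noise();
              if (target == center) continue;
              label = 0.0;
            }
            double* w = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v[k] * w[k];
            const double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < dim; ++k) { neu1e[k] += g * w[k]; w[k] += g * v[k]; }
          }
          for (int k = 0; k < dim; ++k) v[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  return out;
}
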