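// TransE / Weighted TransE trainer.
// Margin-ranking loss over corrupted triplets, minibatch SGD. The weighted
// variant divides the positive triplet's energy by its confidence f in
// (0, 1]; with every f = 1 the arithmetic is identical to unweighted
// training. Entity embeddings are renormalized to unit L2 after every
// minibatch update. Per-example gradient steps are clipped to unit L2 norm:
// the 1/f factor can reach 1/f_min, and unclipped steps of size alpha/f
// destabilize SGD (for L2 energies the unweighted gradient already has
// norm exactly 1, so clipping leaves unweighted runs untouched).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
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

inline void l2_renorm(double* v, int k) {
  double n = 0.0;
  for (int i = 0; i < k; ++i) n += v[i] * v[i];
  n = std::sqrt(n);
  if (n > 0.0) for (int i = 0; i < k; ++i) v[i] /= n;
}

} // namespace

// h, l, t: 0-based index vectors of the training triplets; f: confidences.
// norm_p: 1 or 2. energy_mode: 0 = divide positive energy by f (the
// weighted formulation; f = 1 throughout for unweighted), 1 = multiply
// by f (ablation).
// [[Rcpp::export(name = ".transe_train_cpp")]]
List transe_train_cpp(IntegerVector h, IntegerVector l, IntegerVector t,
                      NumericVector f, int n_entities, int n_relations,
                      int dim, double margin, int norm_p, double alpha,
                      int batch_size, int epochs, int negatives,
                      int energy_mode, int seed) {
  const int n = h.size();
  if (n < 1) stop("empty training set");
  if (n_entities < 2) stop("need at least two entities to corrupt triplets");

  XorShift64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  const double bound = 6.0 / std::sqrt(static_cast<double>(dim));
  std::vector<double> ent(static_cast<size_t>(n_entities) * dim);
  std::vector<double> rel(static_cast<size_t>(n_relations) * dim);
  for (auto& x : ent) x = (rng.unif() * 2.0 - 1.0) * bound;
  for (auto& x : rel) x = (rng.unif() * 2.0 - 1.0) * bound;
  for (int r = 0; r < n_relations; ++r) l2_renorm(&rel[static_cast<size_t>(r) * dim], dim);
  for (int e = 0; e < n_entities; ++e) l2_renorm(&ent[static_cast<size_t>(e) * dim], dim);

  std::vector<double> res(dim), res_neg(dim), grad(dim), grad_neg(dim);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector loss_hist(epochs);
  std::vector<int> touched;

  // residual r = h + l - t; returns energy, fills gradient d(energy)/d(r)
  auto residual_energy = [&](int hi, int li, int ti, std::vector<double>& r,
                             std::vector<double>& g) {
    const double* eh = &ent[static_cast<size_t>(hi) * dim];
    const double* el = &rel[static_cast<size_t>(li) * dim];
    const double* et = &ent[static_cast<size_t>(ti) * dim];
    double d = 0.0;
    for (int k = 0; k < dim; ++k) r[k] = eh[k] + el[k] - et[k];
    if (norm_p == 1) {
      for (int k = 0; k < dim; ++k) {
        d += std::fabs(r[k]);
        g[k] = (r[k] > 0.0) ? 1.0 : ((r[k] < 0.0) ? -1.0 : 0.0);
      }
    } else {
      for (int k = 0; k < dim; ++k) d += r[k] * r[k];
      d = std::sqrt(d);
      const double inv = (d > 1e-12) ? 1.0 / d : 0.0;
      for (int k = 0; k < dim; ++k) g[k] = r[k] * inv;
    }
    return d;
  };

  auto clip_unit = [&](std::vector<double>& g, double scale) {
    // effective gradient is scale * g; cap its L2 norm at 1
    double nn = 0.0;
    for (int k = 0; k < dim; ++k) nn += g[k] * g[k];
    nn = std::sqrt(nn) * std::fabs(scale);
    double s = (nn > 1.0) ? scale / nn : scale;
    for (int k = 0; k < dim; ++k) g[k] *= s;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);
    double ep_loss = 0.0;
    double ep_pairs = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop_at = std::min(start + batch_size, n);
      touched.clear();
      for (int b = start; b < stop_at; ++b) {
        const int i = order[b];
        for (int neg = 0; neg < negatives; ++neg) {
          // corrupt head or tail, never both, never the relation
          int ch = h[i], ct = t[i];
          if (rng.unif() < 0.5) {
            do { ch = rng.below(n_entities); } while (ch == h[i]);
          } else {
            do { ct = rng.below(n_entities); } while (ct == t[i]);
          }
          double d_pos = residual_energy(h[i], l[i], t[i], res, grad);
          double d_neg = residual_energy(ch, l[i], ct, res_neg, grad_neg);
          const double fi = f[i];
          const double d_pos_w = (energy_mode == 1) ? d_pos * fi : d_pos / fi;
          const double viol = margin + d_pos_w - d_neg;
          ep_pairs += 1.0;
          if (viol > 0.0) {
            ep_loss += viol;
            const double wpos = (energy_mode == 1) ? fi : 1.0 / fi;
            clip_unit(grad, wpos);       // d(d_pos_w)/d(residual), clipped
            // positive: descend => h -= a*g, l -= a*g, t += a*g
            double* eh = &ent[static_cast<size_t>(h[i]) * dim];
            double* el = &rel[static_cast<size_t>(l[i]) * dim];
            double* et = &ent[static_cast<size_t>(t[i]) * dim];
            for (int k = 0; k < dim; ++k) {
              const double g = alpha * grad[k];
              eh[k] -= g; el[k] -= g; et[k] += g;
            }
            // negative: ascend its energy
            double* neh = &ent[static_cast<size_t>(ch) * dim];
            double* nel = &rel[static_cast<size_t>(l[i]) * dim];
            double* net = &ent[static_cast<size_t>(ct) * dim];
            for (int k = 0; k < dim; ++k) {
              const double g = alpha * grad_neg[k];
              neh[k] += g; nel[k] += g; net[k] -= g;
            }
            touched.push_back(h[i]); touched.push_back(t[i]);
            touched.push_back(ch);   touched.push_back(ct);
          }
        }
      }
      std::sort(touched.begin(), touched.end());
      touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
      for (int e : touched) l2_renorm(&ent[static_cast<size_t>(e) * dim], dim);
    }
    loss_hist[ep] = (ep_pairs > 0.0) ? ep_loss / ep_pairs : 0.0;
  }

  NumericMatrix ents(n_entities, dim), rels(n_relations, dim);
  for (int i = 0; i < n_entities; ++i)
    for (int k = 0; k < dim; ++k) ents(i, k) = ent[static_cast<size_t>(i) * dim + k];
  for (int i = 0; i < n_relations; ++i)
    for (int k = 0; k < dim; ++k) rels(i, k) = rel[static_cast<size_t>(i) * dim + k];
  return List::create(_["entities"] = ents, _["relations"] = rels,
                      _["loss"] = loss_hist);
}
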