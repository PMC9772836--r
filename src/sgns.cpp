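#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Minimal deterministic RNG (xorshift64*) so training is reproducible across
// platforms independently of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over pre-generated random walks.
// walks: list of integer vectors with 0-based vocabulary indices.
// Returns the input-vector matrix (n_vocab x dim).
// [[Rcpp::export]]
NumericMatrix sgns_train(List walks, int n_vocab, int dim, int window,
                         int negative, int epochs, double alpha0,
                         double seed) {
  XorShift rng(static_cast<uint64_t>(seed));

  std::vector<double> syn0(static_cast<size_t>(n_vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 negative-sampling table
  std::vector<double> counts(n_vocab, 0.0);
  long total_tokens = 0;
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector walk = walks[w];
    total_tokens += walk.size();
    for (int j = 0; j < walk.size(); ++j) counts[walk[j]] += 1.0;
  }
  const int table_size = 1 << 17;
  std::vector<int> neg_table(table_size);
  {
    double z = 0.0;
    for (int v = 0; v < n_vocab; ++v) z += std::pow(counts[v], 0.75);
    if (z <= 0.0) z = 1.0;
    double cum = std::pow(counts[0], 0.75) / z;
    int v = 0;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = v;
      if ((i + 1.0) / table_size > cum && v < n_vocab - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / z;
      }
    }
  }

  std::vector<double> grad(dim);
  const double total_steps =
      std::max(1.0, static_cast<double>(total_tokens) * epochs);
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < walks.size(); ++w) {
      IntegerVector walk = walks[w];
      const int len = walk.size();
      for (int i = 0; i < len; ++i) {
        processed += 1.0;
        double alpha = alpha0 * (1.0 - processed / (total_steps + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        int reduced = rng.below(window) ;  // dynamic window, word2vec-style
        int lo = i - window + reduced; if (lo < 0) lo = 0;
        int hi = i + window - reduced; if (hi > len - 1) hi = len - 1;
        const int center = walk[i];
        double* v_in = &syn0[static_cast<size_t>(center) * dim];
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          const int ctx = walk[j];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int tgt; double lab;
            if (k == 0) { tgt = ctx; lab = 1.0; }
            else {
              tgt = neg_table[rng.below(table_size)];
              if (tgt == ctx) continue;
              lab = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(tgt) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (lab - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_vocab, dim);
  for (int v = 0; v < n_vocab; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[static_cast<size_t>(v) * dim + d];
  return out;
}
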