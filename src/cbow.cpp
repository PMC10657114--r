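#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Self-contained deterministic RNG so that fits are reproducible across
// platforms and independent of R's RNG state.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double unif01(uint64_t &s) {
  // 53-bit mantissa draw in [0, 1)
  return (double)(xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// CBOW with negative sampling over pre-indexed sentences (0-based word ids).
// Mirrors the classic word2vec formulation: the context mean predicts the
// centre word; `negative` noise words are drawn from the unigram^{3/4}
// distribution; the dynamic window shrinks uniformly per position.
// Returns the input-projection matrix (vocab x dim), the usual lookup table.
// [[Rcpp::export]]
NumericMatrix cbow_train_cpp(List sentences,
                             int vocab_size,
                             NumericVector counts,
                             int dim,
                             int window,
                             int epochs,
                             int negative,
                             double lr0,
                             double lr_min,
                             int seed) {
  if (vocab_size < 1) stop("empty vocabulary");
  if (dim < 1) stop("dimension must be >= 1");

  uint64_t rng = (uint64_t)seed * 2654435761u + 88172645463325252ull;

  // unigram^0.75 sampling table
  const int table_size = 100000;
  std::vector<int> neg_table(table_size);
  {
    double total = 0.0;
    for (int w = 0; w < vocab_size; ++w) total += std::pow(counts[w], 0.75);
    int w = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = w;
      if ((double)(i + 1) / table_size > cum && w < vocab_size - 1) {
        ++w;
        cum += std::pow(counts[w], 0.75) / total;
      }
    }
  }

  // syn0: input vectors (the embedding table); syn1: output (context) vectors
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  // pre-extract sentence index vectors
  int n_sent = sentences.size();
  std::vector<std::vector<int> > sent(n_sent);
  long long total_tokens = 0;
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = sentences[s];
    sent[s].assign(iv.begin(), iv.end());
    total_tokens += iv.size();
  }
  if (total_tokens == 0) stop("corpus contains no in-vocabulary tokens");

  const long long total_steps = (long long)epochs * total_tokens;
  long long step = 0;
  std::vector<double> neu1(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int> &sn = sent[s];
      const int len = (int)sn.size();
      for (int t = 0; t < len; ++t) {
        double lr = lr0 * (1.0 - (double)step / (double)(total_steps + 1));
        if (lr < lr_min) lr = lr_min;
        ++step;

        const int centre = sn[t];
        const int b = (int)(xorshift64(rng) % (uint64_t)window);
        const int win = window - b;
        int lo = t - win; if (lo < 0) lo = 0;
        int hi = t + win; if (hi > len - 1) hi = len - 1;

        int cw = 0;
        std::fill(neu1.begin(), neu1.end(), 0.0);
        for (int j = lo; j <= hi; ++j) {
          if (j == t) continue;
          const double *v = &syn0[(size_t)sn[j] * dim];
          for (int d = 0; d < dim; ++d) neu1[d] += v[d];
          ++cw;
        }
        if (cw == 0) continue;
        for (int d = 0; d < dim; ++d) neu1[d] /= cw;

        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int target; double label;
          if (k == 0) {
            target = centre; label = 1.0;
          } else {
            target = neg_table[xorshift64(rng) % (uint64_t)table_size];
            if (target == centre) continue;
            label = 0.0;
          }
          double *out = &syn1[(size_t)target * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += neu1[d] * out[d];
          const double g = (label - sigmoid(f)) * lr;
          for (int d = 0; d < dim; ++d) neu1e[d] += g * out[d];
          for (int d = 0; d < dim; ++d) out[d] += g * neu1[d];
        }
        for (int j = lo; j <= hi; ++j) {
          if (j == t) continue;
          double *v = &syn0[(size_t)sn[j] * dim];
          for (int d = 0; d < dim; ++d) v[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d)
      out(w, d) = syn0[(size_t)w * dim + d];
  return out;
}
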