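#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 64-bit FNV-1a of a NUL-terminated byte string.
static inline uint64_t fnv1a64(const char *s) {
  uint64_t h = 14695981039346656037ULL;
  for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
    h ^= (uint64_t)(*p);
    h *= 1099511628211ULL;
  }
  return h;
}

// Hash each key into [0, n_buckets). Used for bigram feature bucketing;
// fixed algorithm so bucket assignments are stable across platforms.
// [[Rcpp::export]]
IntegerVector cpp_fnv1a_bucket(CharacterVector keys, int n_buckets) {
  if (n_buckets <= 0) stop("n_buckets must be positive");
  R_xlen_t n = keys.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = (int)(fnv1a64(CHAR(STRING_ELT(keys, i))) % (uint64_t)n_buckets);
  }
  return out;
}

// Mean embedding vector per sentence. Features are given in CSR layout:
// feat holds 0-based row indices into E, offsets has length n_sentences + 1.
// Sentences with no features get the zero vector.
// [[Rcpp::export]]
NumericMatrix cpp_sentence_vectors(NumericMatrix E, IntegerVector feat,
                                   IntegerVector offsets) {
  int dim = E.ncol();
  int n = offsets.size() - 1;
  NumericMatrix V(n, dim);
  for (int i = 0; i < n; ++i) {
    int from = offsets[i], to = offsets[i + 1];
    int nf = to - from;
    if (nf == 0) continue;
    for (int f = from; f < to; ++f) {
      int r = feat[f];
      for (int d = 0; d < dim; ++d) V(i, d) += E(r, d);
    }
    for (int d = 0; d < dim; ++d) V(i, d) /= nf;
  }
  return V;
}

// Stochastic gradient descent on binary logistic loss over mean-of-embedding
// sentence vectors, updating both the logistic weights and the contributing
// embedding rows (fastText-style supervised training). The learning rate
// decays linearly to zero over all updates. `orders` is an n x epochs matrix
// of 0-based sentence visit orders, generated (seeded) on the R side so the
// whole procedure is deterministic.
// [[Rcpp::export]]
List cpp_sgd_train(NumericMatrix E_, IntegerVector feat, IntegerVector offsets,
                   IntegerVector y, IntegerMatrix orders, double lr0) {
  NumericMatrix E = clone(E_);
  int dim = E.ncol();
  int n = offsets.size() - 1;
  int epochs = orders.ncol();
  if (orders.nrow() != n) stop("orders must have one row per sentence");
  NumericVector w(dim);
  double b = 0.0;
  std::vector<double> h(dim), wold(dim);
  double total = (double)epochs * (double)n;
  double t = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s, t += 1.0) {
      int i = orders(s, e);
      double lr = lr0 * (1.0 - t / total);
      int from = offsets[i], to = offsets[i + 1];
      int nf = to - from;
      double z = b;
      if (nf > 0) {
        std::fill(h.begin(), h.end(), 0.0);
        for (int f = from; f < to; ++f) {
          int r = feat[f];
          for (int d = 0; d < dim; ++d) h[d] += E(r, d);
        }
        for (int d = 0; d < dim; ++d) {
          h[d] /= nf;
          z += w[d] * h[d];
        }
      }
      double p = 1.0 / (1.0 + std::exp(-z));
      double g = lr * (p - (double)y[i]);
      if (nf > 0) {
        for (int d = 0; d < dim; ++d) wold[d] = w[d];
        for (int d = 0; d < dim; ++d) w[d] -= g * h[d];
        double scale = g / nf;
        for (int f = from; f < to; ++f) {
          int r = feat[f];
          for (int d = 0; d < dim; ++d) E(r, d) -= scale * wold[d];
        }
      }
      b -= g;
    }
  }
  return List::create(_["weights"] = w, _["bias"] = b, _["embeddings"] = E);
}

// Skipgram with negative sampling. tokens: 0-based word ids, concatenated
// sentences; sent_offsets: CSR offsets per sentence. Uin_ holds the (seeded,
// R-initialised) input vectors; output vectors start at zero. neg_table is a
// precomputed unigram^(3/4) sampling table of 0-based word ids. All internal
// randomness comes from a xorshift generator seeded by `seed`, so results
// are deterministic and platform-independent.
// [[Rcpp::export]]
NumericMatrix cpp_skipgram(IntegerVector tokens, IntegerVector sent_offsets,
                           NumericMatrix Uin_, IntegerVector neg_table,
                           int window, int negative, int epochs, double lr0,
                           double seed) {
  NumericMatrix Uin = clone(Uin_);
  int dim = Uin.ncol();
  int V = Uin.nrow();
  if (tokens.size() == 0) stop("empty corpus");
  std::vector<double> Uout((size_t)V * dim, 0.0);
  uint64_t rng = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;
  auto nextrand = [&]() {
    rng ^= rng << 13;
    rng ^= rng >> 7;
    rng ^= rng << 17;
    return rng;
  };
  int ntab = neg_table.size();
  int nsent = sent_offsets.size() - 1;
  double total = (double)epochs * (double)tokens.size();
  double t = 0.0;
  std::vector<double> grad(dim);
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < nsent; ++s) {
      int from = sent_offsets[s], to = sent_offsets[s + 1];
      for (int pos = from; pos < to; ++pos, t += 1.0) {
        double lr = lr0 * (1.0 - t / total);
        if (lr < 1e-4 * lr0) lr = 1e-4 * lr0;
        int wid = tokens[pos];
        int b = 1 + (int)(nextrand() % (uint64_t)window);
        for (int c = pos - b; c <= pos + b; ++c) {
          if (c < from || c >= to || c == pos) continue;
          int ctx = tokens[c];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = neg_table[(int)(nextrand() % (uint64_t)ntab)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double *out = &Uout[(size_t)target * dim];
            double z = 0.0;
            for (int d = 0; d < dim; ++d) z += Uin(wid, d) * out[d];
            double p = 1.0 / (1.0 + std::exp(-z));
            double g = lr * (label - p);
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * out[d];
              out[d] += g * Uin(wid, d);
            }
          }
          for (int d = 0; d < dim; ++d) Uin(wid, d) += grad[d];
        }
      }
    }
  }
  return Uin;
}
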