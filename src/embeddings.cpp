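// Negative-sampling embedding trainers: PV-DM (paragraph vectors over k-mer
// tokens) and skip-gram (role sequences from random walks). Single-threaded
// on purpose: training must be bitwise-reproducible for a fixed seed.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// splitmix-style 64-bit generator; avoids std::*_distribution whose output
// is not pinned down by the C++ standard across library implementations.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

// sigmoid via a fixed lookup table over [-6, 6] (word2vec-style); cheaper
// than exp() in the inner loop and still deterministic.
struct SigTable {
  static const int N = 1024;
  double tab[N + 1];
  SigTable() {
    for (int i = 0; i <= N; ++i) {
      double x = (i * 12.0 / N) - 6.0;
      tab[i] = 1.0 / (1.0 + std::exp(-x));
    }
  }
};
static const SigTable SIG;

inline double sigmoid(double x) {
  if (x >= 6.0) return 1.0;
  if (x <= -6.0) return 0.0;
  return SIG.tab[(int)((x + 6.0) * (SigTable::N / 12.0))];
}

// cumulative unigram^pow table for negative sampling
std::vector<double> neg_table(const std::vector<double>& counts, double pw) {
  std::vector<double> cum(counts.size());
  double tot = 0.0;
  for (size_t i = 0; i < counts.size(); ++i) {
    tot += std::pow(counts[i], pw);
    cum[i] = tot;
  }
  for (size_t i = 0; i < cum.size(); ++i) cum[i] /= tot;
  return cum;
}

inline int draw_neg(Rng& rng, const std::vector<double>& cum) {
  double u = rng.unif();
  return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// one PV-DM step at position t of a token sequence: context mean h includes
// the doc vector and the window words; SGNS update against the output matrix.
// If train_words is false (inference) only the doc vector receives gradient.
void pvdm_step(const std::vector<int>& toks, int t, int window, int negative,
               double lr, double* doc, std::vector<double>& word,
               std::vector<double>& out, int dim,
               const std::vector<double>& cum, Rng& rng, bool train_words) {
  int n = (int)toks.size();
  int lo = std::max(0, t - window), hi = std::min(n - 1, t + window);
  std::vector<int> ctx;
  for (int j = lo; j <= hi; ++j) if (j != t) ctx.push_back(toks[j]);
  int m = (int)ctx.size() + 1;  // + doc vector
  std::vector<double> h(dim, 0.0), grad(dim, 0.0);
  for (int d = 0; d < dim; ++d) h[d] = doc[d];
  for (int c : ctx)
    for (int d = 0; d < dim; ++d) h[d] += word[(size_t)c * dim + d];
  for (int d = 0; d < dim; ++d) h[d] /= m;

  int target = toks[t];
  for (int k = 0; k <= negative; ++k) {
    int w; double label;
    if (k == 0) { w = target; label = 1.0; }
    else {
      w = draw_neg(rng, cum);
      if (w == target) continue;
      label = 0.0;
    }
    double* ow = &out[(size_t)w * dim];
    double f = 0.0;
    for (int d = 0; d < dim; ++d) f += h[d] * ow[d];
    double g = (label - sigmoid(f)) * lr;
    for (int d = 0; d < dim; ++d) {
      grad[d] += g * ow[d];
      if (train_words) ow[d] += g * h[d];
    }
  }
  for (int d = 0; d < dim; ++d) doc[d] += grad[d] / m;
  if (train_words)
    for (int c : ctx) {
      double* wv = &word[(size_t)c * dim];
      for (int d = 0; d < dim; ++d) wv[d] += grad[d] / m;
    }
}

}  // namespace

// [[Rcpp::export]]
List cpp_pvdm_train(List docs, int vocab_size, int dim, int window,
                    int epochs, int negative, double alpha, double min_alpha,
                    int seed) {
  int n_docs = docs.size();
  std::vector<std::vector<int>> dd(n_docs);
  std::vector<double> counts(vocab_size, 0.0);
  long long total = 0;
  for (int i = 0; i < n_docs; ++i) {
    IntegerVector v = docs[i];
    dd[i].assign(v.begin(), v.end());
    for (int t : dd[i]) { counts[t] += 1.0; ++total; }
  }
  if (total == 0) stop("empty corpus");
  std::vector<double> cum = neg_table(counts, 0.75);

  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> word((size_t)vocab_size * dim), out((size_t)vocab_size * dim, 0.0);
  std::vector<double> doc((size_t)n_docs * dim);
  for (auto& x : word) x = (rng.unif() - 0.5) / dim;
  for (auto& x : doc) x = (rng.unif() - 0.5) / dim;

  long long steps = (long long)epochs * total, done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_docs; ++i) {
      const std::vector<int>& toks = dd[i];
      for (int t = 0; t < (int)toks.size(); ++t) {
        double lr = alpha + (min_alpha - alpha) * ((double)done / steps);
        pvdm_step(toks, t, window, negative, lr, &doc[(size_t)i * dim],
                  word, out, dim, cum, rng, true);
        ++done;
      }
    }
  }
  NumericMatrix W(dim, vocab_size), O(dim, vocab_size), D(dim, n_docs);
  std::copy(word.begin(), word.end(), W.begin());
  std::copy(out.begin(), out.end(), O.begin());
  std::copy(doc.begin(), doc.end(), D.begin());
  return List::create(_["word"] = W, _["out"] = O, _["doc"] = D,
                      _["counts"] = NumericVector(counts.begin(), counts.end()));
}

// [[Rcpp::export]]
NumericVector cpp_pvdm_infer(IntegerVector tokens, NumericMatrix word_m,
                             NumericMatrix out_m, NumericVector counts_v,
                             int window, int epochs, int negative,
                             double alpha, double min_alpha, int seed) {
  int dim = word_m.nrow(), vocab = word_m.ncol();
  std::vector<int> toks(tokens.begin(), tokens.end());
  if (toks.empty()) stop("no tokens to infer from");
  std::vector<double> word(word_m.begin(), word_m.end());
  std::vector<double> out(out_m.begin(), out_m.end());
  std::vector<double> counts(counts_v.begin(), counts_v.end());
  if ((int)counts.size() != vocab) stop("counts/vocab mismatch");
  std::vector<double> cum = neg_table(counts, 0.75);

  Rng rng((uint64_t)seed * 2654435761ULL + 7ULL);
  std::vector<double> doc(dim);
  for (auto& x : doc) x = (rng.unif() - 0.5) / dim;
  long long steps = (long long)epochs * toks.size(), done = 0;
  for (int ep = 0; ep < epochs; ++ep)
    for (int t = 0; t < (int)toks.size(); ++t) {
      double lr = alpha + (min_alpha - alpha) * ((double)done / steps);
      pvdm_step(toks, t, window, negative, lr, doc.data(), word, out, dim,
                cum, rng, false);
      ++done;
    }
  return NumericVector(doc.begin(), doc.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(List seqs, int vocab_size, int dim, int window,
                             int epochs, int negative, double alpha,
                             double min_alpha, int seed) {
  int n_seq = seqs.size();
  std::vector<std::vector<int>> ss(n_seq);
  std::vector<double> counts(vocab_size, 0.0);
  long long total = 0;
  for (int i = 0; i < n_seq; ++i) {
    IntegerVector v = seqs[i];
    ss[i].assign(v.begin(), v.end());
    for (int t : ss[i]) { counts[t] += 1.0; ++total; }
  }
  if (total == 0) stop("empty walk corpus");
  for (auto& c : counts) if (c == 0.0) c = 1e-12;  // keep table well-defined
  std::vector<double> cum = neg_table(counts, 0.75);

  Rng rng((uint64_t)seed * 2654435761ULL + 13ULL);
  std::vector<double> in((size_t)vocab_size * dim), out((size_t)vocab_size * dim, 0.0);
  for (auto& x : in) x = (rng.unif() - 0.5) / dim;

  long long steps = (long long)epochs * total, done = 0;
  for (int ep = 0; ep < epochs; ++ep)
    for (int i = 0; i < n_seq; ++i) {
      const std::vector<int>& toks = ss[i];
      int n = (int)toks.size();
      for (int t = 0; t < n; ++t) {
        double lr = alpha + (min_alpha - alpha) * ((double)done / steps);
        ++done;
        int lo = std::max(0, t - window), hi = std::min(n - 1, t + window);
        double* vin = &in[(size_t)toks[t] * dim];
        for (int j = lo; j <= hi; ++j) {
          if (j == t) continue;
          int target = toks[j];
          std::vector<double> grad(dim, 0.0);
          for (int k = 0; k <= negative; ++k) {
            int w; double label;
            if (k == 0) { w = target; label = 1.0; }
            else {
              w = draw_neg(rng, cum);
              if (w == target) continue;
              label = 0.0;
            }
            double* ow = &out[(size_t)w * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += vin[d] * ow[d];
            double g = (label - sigmoid(f)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * ow[d];
              ow[d] += g * vin[d];
            }
          }
          for (int d = 0; d < dim; ++d) vin[d] += grad[d];
        }
      }
    }
  NumericMatrix M(dim, vocab_size);
  std::copy(in.begin(), in.end(), M.begin());
  return M;
}
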