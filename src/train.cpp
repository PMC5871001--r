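#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-threaded SGD loop for CBOW / skip-gram with hierarchical softmax.
// Arithmetic mirrors the pure-R reference trainer operation-for-operation
// (long-double dot accumulation matches R's sum()), so the two engines
// produce the same model on the same inputs.

static inline double dot_ld(const double* a, const double* b, int n) {
  long double acc = 0.0L;
  for (int i = 0; i < n; ++i) acc += a[i] * b[i];
  return (double)acc;
}

// [[Rcpp::export]]
List train_loop_cpp(List sent, NumericMatrix syn0_in, NumericMatrix syn1_in,
                    IntegerVector code_len, IntegerVector codes_flat,
                    IntegerVector paths_flat, bool cbow, int window,
                    int epochs, double initial_lr, double min_lr) {
  NumericMatrix syn0 = clone(syn0_in);
  NumericMatrix syn1 = clone(syn1_in);
  const int dim = syn0.nrow();
  const int nv = syn0.ncol();

  std::vector<int> code_off(nv + 1, 0);
  for (int i = 0; i < nv; ++i) code_off[i + 1] = code_off[i] + code_len[i];

  std::vector<std::vector<int> > sents;
  long n_tokens = 0;
  for (int i = 0; i < sent.size(); ++i) {
    IntegerVector s = sent[i];
    std::vector<int> v(s.size());
    for (int j = 0; j < s.size(); ++j) v[j] = s[j] - 1;  // 0-based
    n_tokens += v.size();
    sents.push_back(v);
  }
  const double total = (double)epochs * (double)n_tokens;

  NumericVector epoch_loss(epochs);
  NumericVector epoch_pairs(epochs);
  std::vector<double> h(dim), neu1e(dim);
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0, pairs = 0.0;
    for (size_t si = 0; si < sents.size(); ++si) {
      const std::vector<int>& s = sents[si];
      const int n = (int)s.size();
      for (int t = 0; t < n; ++t) {
        double alpha = initial_lr - (initial_lr - min_lr) * (processed / total);
        if (alpha < min_lr) alpha = min_lr;
        processed += 1.0;
        int lo = t - window; if (lo < 0) lo = 0;
        int hi = t + window; if (hi > n - 1) hi = n - 1;
        int cn = hi - lo + 1 - 1;  // window members minus the center itself
        if (cn <= 0) continue;
        if (cbow) {
          for (int i = 0; i < dim; ++i) h[i] = 0.0;
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            const double* col = &syn0(0, s[j]);
            for (int i = 0; i < dim; ++i) h[i] += col[i];
          }
          for (int i = 0; i < dim; ++i) h[i] /= (double)cn;
          const int w = s[t];
          for (int i = 0; i < dim; ++i) neu1e[i] = 0.0;
          for (int k = 0; k < code_len[w]; ++k) {
            const int kk = code_off[w] + k;
            const int node = paths_flat[kk] - 1;
            double* v = &syn1(0, node);
            const double f = 1.0 / (1.0 + std::exp(-dot_ld(v, h.data(), dim)));
            const double tk = (codes_flat[kk] == 0) ? 1.0 : 0.0;
            const double g = f - tk;
            loss += -std::log(tk == 1.0 ? f : 1.0 - f);
            for (int i = 0; i < dim; ++i) neu1e[i] += g * v[i];
            const double ag = alpha * g;
            for (int i = 0; i < dim; ++i) v[i] -= ag * h[i];
          }
          pairs += 1.0;
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            double* col = &syn0(0, s[j]);
            for (int i = 0; i < dim; ++i) col[i] -= alpha * (neu1e[i] / cn);
          }
        } else {
          const double* hc = &syn0(0, s[t]);
          for (int i = 0; i < dim; ++i) h[i] = hc[i];
          for (int i = 0; i < dim; ++i) neu1e[i] = 0.0;
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            const int w = s[j];
            for (int k = 0; k < code_len[w]; ++k) {
              const int kk = code_off[w] + k;
              const int node = paths_flat[kk] - 1;
              double* v = &syn1(0, node);
              const double f = 1.0 / (1.0 + std::exp(-dot_ld(v, h.data(), dim)));
              const double tk = (codes_flat[kk] == 0) ? 1.0 : 0.0;
              const double g = f - tk;
              loss += -std::log(tk == 1.0 ? f : 1.0 - f);
              for (int i = 0; i < dim; ++i) neu1e[i] += g * v[i];
              const double ag = alpha * g;
              for (int i = 0; i < dim; ++i) v[i] -= ag * h[i];
            }
            pairs += 1.0;
          }
          double* col = &syn0(0, s[t]);
          for (int i = 0; i < dim; ++i) col[i] = h[i] - alpha * neu1e[i];
        }
      }
    }
    epoch_loss[ep] = loss;
    epoch_pairs[ep] = pairs;
  }
  return List::create(_["syn0"] = syn0, _["syn1"] = syn1,
                      _["epoch_loss"] = epoch_loss,
                      _["epoch_pairs"] = epoch_pairs);
}
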