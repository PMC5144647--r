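#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and fully deterministic
// given `seed`. Uniform variates are derived directly from mt19937 output
// words so results do not depend on a standard library's distribution
// implementation. Learning rate decays linearly over all training tokens to
// alpha_min.

static inline double next_unif(std::mt19937 &gen) {
  // 32 random bits -> [0, 1)
  return gen() * (1.0 / 4294967296.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0 - 1e-12;
  if (x < -8.0) return 1e-12;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export(name = ".sgns_train")]]
List sgns_train(List sentences, int vocab_size, int dim, int window,
                int negative, int epochs, double alpha, double alpha_min,
                NumericVector noise_cdf, int seed, bool dynamic_window) {
  const int V = vocab_size, d = dim;
  std::mt19937 gen(static_cast<uint32_t>(seed));

  // word (input) and context (output) matrices, row-major V x d
  std::vector<double> syn0(static_cast<size_t>(V) * d);
  std::vector<double> syn1(static_cast<size_t>(V) * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (next_unif(gen) - 0.5) / d;

  // precompute total tokens for the lr schedule
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_tokens += Rf_length(sentences[s]);
  total_tokens *= epochs;
  if (total_tokens < 1) total_tokens = 1;

  const double *cdf = noise_cdf.begin();
  const int ncdf = noise_cdf.size();
  std::vector<double> grad(d);
  long long seen = 0;
  double loss = 0.0;
  NumericVector epoch_loss(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    loss = 0.0;
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int m = sent.size();
      for (int pos = 0; pos < m; ++pos) {
        const int centre = sent[pos];
        const double lr = std::max(
            alpha * (1.0 - static_cast<double>(seen) / total_tokens), alpha_min);
        ++seen;
        if (centre < 0 || centre >= V) continue;
        int win = window;
        if (dynamic_window)
          win = 1 + static_cast<int>(next_unif(gen) * window);
        if (win > window) win = window;
        const int lo = std::max(0, pos - win);
        const int hi = std::min(m - 1, pos + win);
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          const int target = sent[cpos];
          if (target < 0 || target >= V) continue;
          double *v_in = &syn0[static_cast<size_t>(centre) * d];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int out;
            double label;
            if (k == 0) {
              out = target;
              label = 1.0;
            } else {
              const double u = next_unif(gen);
              out = static_cast<int>(
                  std::lower_bound(cdf, cdf + ncdf, u) - cdf);
              if (out >= ncdf) out = ncdf - 1;
              if (out == target) continue;
              label = 0.0;
            }
            double *v_out = &syn1[static_cast<size_t>(out) * d];
            double dot = 0.0;
            for (int j = 0; j < d; ++j) dot += v_in[j] * v_out[j];
            const double p = sigmoid(dot);
            loss -= label > 0.5 ? std::log(p) : std::log(1.0 - p);
            const double g = (label - p) * lr;
            for (int j = 0; j < d; ++j) {
              grad[j] += g * v_out[j];
              v_out[j] += g * v_in[j];
            }
          }
          for (int j = 0; j < d; ++j) v_in[j] += grad[j];
        }
      }
    }
    epoch_loss[ep] = loss;
  }

  NumericMatrix W(V, d), C(V, d);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < d; ++j) {
      W(i, j) = syn0[static_cast<size_t>(i) * d + j];
      C(i, j) = syn1[static_cast<size_t>(i) * d + j];
    }
  return List::create(_["word"] = W, _["context"] = C,
                      _["epoch_loss"] = epoch_loss);
}
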