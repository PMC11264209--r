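// Single-hidden-layer ReLU network for binary classification, trained with
// Adam on a weighted cross-entropy loss with L2 penalty on the weights.
// Deterministic for a fixed seed (own RNG for init and shuffling).
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

namespace {
struct MlpRng {
  std::mt19937_64 eng;
  explicit MlpRng(uint64_t seed) : eng(seed) {}
  double unif() {
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};
} // namespace

// [[Rcpp::export]]
List cpp_mlp_train(NumericMatrix X, NumericVector y, NumericVector w,
                   int n_hidden, double learning_rate, double l2,
                   int batch_size, int epochs, double seed) {
  int n = X.nrow(), p = X.ncol(), H = n_hidden;
  MlpRng rng(static_cast<uint64_t>(seed));

  // Glorot-uniform init
  std::vector<double> W1(size_t(p) * H), b1(H, 0.0), W2(H), b2(1, 0.0);
  double lim1 = std::sqrt(6.0 / (p + H)), lim2 = std::sqrt(6.0 / (H + 1));
  for (auto& v : W1) v = (2.0 * rng.unif() - 1.0) * lim1;
  for (auto& v : W2) v = (2.0 * rng.unif() - 1.0) * lim2;

  size_t npar = W1.size() + b1.size() + W2.size() + 1;
  std::vector<double> m(npar, 0.0), v2(npar, 0.0);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  double wsum_all = std::accumulate(w.begin(), w.end(), 0.0);

  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<double> h(H), gW1(W1.size()), gb1(H), gW2(H);
  long adam_t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      std::fill(gW1.begin(), gW1.end(), 0.0);
      std::fill(gb1.begin(), gb1.end(), 0.0);
      std::fill(gW2.begin(), gW2.end(), 0.0);
      double gb2 = 0.0, wbatch = 0.0;
      for (int b = start; b < end; ++b) {
        int i = idx[b];
        wbatch += w[i];
        for (int k = 0; k < H; ++k) {
          double z = b1[k];
          for (int j = 0; j < p; ++j) z += X(i, j) * W1[size_t(j) * H + k];
          h[k] = z > 0.0 ? z : 0.0;
        }
        double z2 = b2[0];
        for (int k = 0; k < H; ++k) z2 += h[k] * W2[k];
        double pr = 1.0 / (1.0 + std::exp(-z2));
        double d2 = w[i] * (pr - y[i]); // dL/dz2 for weighted BCE
        gb2 += d2;
        for (int k = 0; k < H; ++k) {
          gW2[k] += d2 * h[k];
          if (h[k] > 0.0) {
            double d1 = d2 * W2[k];
            gb1[k] += d1;
            for (int j = 0; j < p; ++j) gW1[size_t(j) * H + k] += d1 * X(i, j);
          }
        }
      }
      if (wbatch <= 0.0) continue;
      double inv = 1.0 / wbatch;
      // L2 on weights only, scaled as penalty/(total weight) per sklearn
      double l2s = l2 / wsum_all;
      ++adam_t;
      double bc1 = 1.0 - std::pow(beta1, adam_t);
      double bc2 = 1.0 - std::pow(beta2, adam_t);
      size_t q = 0;
      auto adam = [&](double* par, double g) {
        m[q] = beta1 * m[q] + (1.0 - beta1) * g;
        v2[q] = beta2 * v2[q] + (1.0 - beta2) * g * g;
        *par -= learning_rate * (m[q] / bc1) / (std::sqrt(v2[q] / bc2) + eps);
        ++q;
      };
      for (size_t j = 0; j < W1.size(); ++j) adam(&W1[j], gW1[j] * inv + l2s * W1[j]);
      for (int k = 0; k < H; ++k) adam(&b1[k], gb1[k] * inv);
      for (int k = 0; k < H; ++k) adam(&W2[k], gW2[k] * inv + l2s * W2[k]);
      adam(&b2[0], gb2 * inv);
    }
  }
  NumericMatrix W1m(p, H);
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < H; ++k) W1m(j, k) = W1[size_t(j) * H + k];
  return List::create(_["W1"] = W1m,
                      _["b1"] = NumericVector(b1.begin(), b1.end()),
                      _["W2"] = NumericVector(W2.begin(), W2.end()),
                      _["b2"] = b2[0]);
}

// [[Rcpp::export]]
NumericVector cpp_mlp_predict(NumericMatrix X, NumericMatrix W1,
                              NumericVector b1, NumericVector W2, double b2) {
  int n = X.nrow(), p = X.ncol(), H = W1.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double z2 = b2;
    for (int k = 0; k < H; ++k) {
      double z = b1[k];
      for (int j = 0; j < p; ++j) z += X(i, j) * W1(j, k);
      if (z > 0.0) z2 += z * W2[k];
    }
    out[i] = 1.0 / (1.0 + std::exp(-z2));
  }
  return out;
}
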