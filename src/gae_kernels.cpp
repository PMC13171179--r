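// Fused inner-loop kernels for autoencoder training. Each replaces a chain
// of whole-matrix R operations with a single pass over the data.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted BCE loss over off-diagonal pairs of sigmoid(u), plus its
// gradient dL/du. a is the dense 0/1 target adjacency. Probabilities are
// clamped to [eps, 1 - eps] inside the logs.
// [[Rcpp::export]]
List bce_loss_grad_cpp(NumericMatrix u, NumericMatrix a, double pos_weight) {
  const int n = u.nrow();
  const double m_off = static_cast<double>(n) * (n - 1);
  const double eps = 1e-7;
  NumericMatrix grad(n, n);
  double loss = 0.0;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      if (i == j) { grad(i, j) = 0.0; continue; }
      const double s = 1.0 / (1.0 + std::exp(-u(i, j)));
      double sc = s;
      if (sc < eps) sc = eps;
      if (sc > 1.0 - eps) sc = 1.0 - eps;
      if (a(i, j) > 0) {
        loss -= pos_weight * std::log(sc);
        grad(i, j) = -pos_weight * (1.0 - s) / m_off;
      } else {
        loss -= std::log1p(-sc);
        grad(i, j) = s / m_off;
      }
    }
  }
  return List::create(_["loss"] = loss / m_off, _["grad"] = grad);
}

// ELU (alpha = 1) and its derivative in one pass.
// [[Rcpp::export]]
List elu_fwd_cpp(NumericMatrix x) {
  const R_xlen_t m = x.size();
  NumericMatrix y(x.nrow(), x.ncol()), g(x.nrow(), x.ncol());
  for (R_xlen_t i = 0; i < m; ++i) {
    const double v = x[i];
    if (v > 0) { y[i] = v; g[i] = 1.0; }
    else { const double e = std::exp(v); y[i] = e - 1.0; g[i] = e; }
  }
  return List::create(_["y"] = y, _["grad"] = g);
}

// Row-wise layer normalisation with affine gain/bias (epsilon = 1e-5).
// [[Rcpp::export]]
List layer_norm_fwd_cpp(NumericMatrix s, NumericVector gain,
                        NumericVector bias) {
  const int n = s.nrow(), h = s.ncol();
  NumericMatrix out(n, h), xhat(n, h);
  NumericVector inv(n);
  for (int i = 0; i < n; ++i) {
    double mu = 0.0;
    for (int j = 0; j < h; ++j) mu += s(i, j);
    mu /= h;
    double var = 0.0;
    for (int j = 0; j < h; ++j) {
      const double d = s(i, j) - mu;
      var += d * d;
    }
    var /= h;
    const double iv = 1.0 / std::sqrt(var + 1e-5);
    inv[i] = iv;
    for (int j = 0; j < h; ++j) {
      const double xh = (s(i, j) - mu) * iv;
      xhat(i, j) = xh;
      out(i, j) = xh * gain[j] + bias[j];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// Backward pass of the row-wise layer normalisation.
// [[Rcpp::export]]
List layer_norm_bwd_cpp(NumericMatrix dy, NumericMatrix xhat,
                        NumericVector inv, NumericVector gain) {
  const int n = dy.nrow(), h = dy.ncol();
  NumericMatrix dx(n, h);
  NumericVector dg(h), db(h);
  for (int i = 0; i < n; ++i) {
    double m1 = 0.0, m2 = 0.0;
    for (int j = 0; j < h; ++j) {
      const double dxh = dy(i, j) * gain[j];
      m1 += dxh;
      m2 += dxh * xhat(i, j);
    }
    m1 /= h;
    m2 /= h;
    for (int j = 0; j < h; ++j) {
      const double dxh = dy(i, j) * gain[j];
      dx(i, j) = inv[i] * (dxh - m1 - xhat(i, j) * m2);
      dg[j] += dy(i, j) * xhat(i, j);
      db[j] += dy(i, j);
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}
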