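#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// WH <- W %*% H, epsilon-floored (all buffers column-major)
static void mat_prod(const double* W, const double* H, double* WH,
                     int n, int m, int k, double eps) {
  for (int j = 0; j < m; ++j) {
    double* whj = WH + (size_t)j * n;
    for (int i = 0; i < n; ++i) whj[i] = 0.0;
    const double* hj = H + (size_t)j * k;
    for (int r = 0; r < k; ++r) {
      double h = hj[r];
      if (h == 0.0) continue;
      const double* wr = W + (size_t)r * n;
      for (int i = 0; i < n; ++i) whj[i] += wr[i] * h;
    }
    for (int i = 0; i < n; ++i) if (whj[i] < eps) whj[i] = eps;
  }
}

// generalized KL divergence D(V || WH); vlogv = precomputed v*log(v) (0 for v=0)
static double kl_div(const double* V, const double* vlogv, const double* WH,
                     size_t nm) {
  double d = 0.0;
  for (size_t t = 0; t < nm; ++t) {
    double v = V[t], wh = WH[t];
    if (v > 0.0) d += vlogv[t] - v * std::log(wh) - v + wh;
    else d += wh;
  }
  return d;
}

// Multiplicative-update NMF for the generalized KL objective
// (Lee & Seung updates, the variant used by Brunet-style consensus NMF).
// Factors are epsilon-floored so they stay strictly positive; the
// objective is recorded after every full (H then W) update and is
// non-increasing.
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
List nmf_kl_cpp(NumericMatrix Vin, NumericMatrix Win, NumericMatrix Hin,
                int max_iter, double tol, double eps) {
  int n = Vin.nrow(), m = Vin.ncol(), k = Win.ncol();
  size_t nm = (size_t)n * m;
  NumericMatrix Wout(clone(Win)), Hout(clone(Hin));
  const double* V = REAL(Vin);
  double* W = REAL(Wout);
  double* H = REAL(Hout);
  std::vector<double> WH(nm), Q(nm), vlogv(nm);
  for (size_t t = 0; t < nm; ++t)
    vlogv[t] = (V[t] > 0.0) ? V[t] * std::log(V[t]) : 0.0;

  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  mat_prod(W, H, WH.data(), n, m, k, eps);
  double prev = kl_div(V, vlogv.data(), WH.data(), nm);
  trace.push_back(prev);

  std::vector<double> num(k), colw(k), rowh(k);
  for (int it = 0; it < max_iter; ++it) {
    // H update: H_rj <- H_rj * sum_i W_ir V_ij / WH_ij / sum_i W_ir
    for (size_t t = 0; t < nm; ++t) Q[t] = V[t] / WH[t];
    for (int r = 0; r < k; ++r) {
      double s = 0.0;
      const double* wr = W + (size_t)r * n;
      for (int i = 0; i < n; ++i) s += wr[i];
      colw[r] = (s < eps) ? eps : s;
    }
    for (int j = 0; j < m; ++j) {
      const double* qj = Q.data() + (size_t)j * n;
      double* hj = H + (size_t)j * k;
      for (int r = 0; r < k; ++r) {
        const double* wr = W + (size_t)r * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += wr[i] * qj[i];
        double h = hj[r] * s / colw[r];
        hj[r] = (h < eps) ? eps : h;
      }
    }
    mat_prod(W, H, WH.data(), n, m, k, eps);
    // W update: W_ir <- W_ir * sum_j V_ij / WH_ij H_rj / sum_j H_rj
    for (size_t t = 0; t < nm; ++t) Q[t] = V[t] / WH[t];
    for (int r = 0; r < k; ++r) rowh[r] = 0.0;
    for (int j = 0; j < m; ++j) {
      const double* hj = H + (size_t)j * k;
      for (int r = 0; r < k; ++r) rowh[r] += hj[r];
    }
    std::vector<double> acc((size_t)n * k, 0.0);
    for (int j = 0; j < m; ++j) {
      const double* qj = Q.data() + (size_t)j * n;
      const double* hj = H + (size_t)j * k;
      for (int r = 0; r < k; ++r) {
        double h = hj[r];
        if (h == 0.0) continue;
        double* ar = acc.data() + (size_t)r * n;
        for (int i = 0; i < n; ++i) ar[i] += qj[i] * h;
      }
    }
    for (int r = 0; r < k; ++r) {
      double d = (rowh[r] < eps) ? eps : rowh[r];
      double* wr = W + (size_t)r * n;
      const double* ar = acc.data() + (size_t)r * n;
      for (int i = 0; i < n; ++i) {
        double w = wr[i] * ar[i] / d;
        wr[i] = (w < eps) ? eps : w;
      }
    }
    mat_prod(W, H, WH.data(), n, m, k, eps);
    double obj = kl_div(V, vlogv.data(), WH.data(), nm);
    trace.push_back(obj);
    double rel = std::fabs(prev - obj) / (std::fabs(prev) + eps);
    prev = obj;
    if (rel < tol) break;
  }
  return List::create(_["W"] = Wout, _["H"] = Hout,
                      _["objective_trace"] = NumericVector(trace.begin(), trace.end()));
}
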