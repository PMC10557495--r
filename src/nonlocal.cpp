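// Embedded-Gaussian non-local (self-attention) block: forward pass and
// hand-derived backward pass. Operates on a batch of patches; Z holds the
// position-wise features of all patches stacked row-wise (N patches * P
// positions) x d. Per-patch products are small (P x da), so they are
// written as explicit loops over row-major scratch buffers (contiguous
// inner dots) rather than BLAS calls, whose per-call overhead dominates at
// this size. Gradient correctness is covered by a finite-difference test
// in the package test suite.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// copy rows [r0, r0+P) of M (arma, col-major) into row-major buf (P x k)
static inline void to_rowmajor(const arma::mat& M, int r0, int P, int k,
                               double* buf) {
  for (int t = 0; t < k; ++t) {
    const double* col = M.colptr(t) + r0;
    for (int i = 0; i < P; ++i) buf[i * k + t] = col[i];
  }
}

static inline void from_rowmajor(arma::mat& M, int r0, int P, int k,
                                 const double* buf) {
  for (int t = 0; t < k; ++t) {
    double* col = M.colptr(t) + r0;
    for (int i = 0; i < P; ++i) col[i] = buf[i * k + t];
  }
}

// [[Rcpp::export(name = ".cpp_nonlocal_forward")]]
List cpp_nonlocal_forward(const arma::mat& Z, int P, const arma::mat& Wq,
                          const arma::mat& Wk, const arma::mat& Wv,
                          const arma::mat& Wo, bool keep_cache = true) {
  const int N = Z.n_rows / P;
  const int da = Wq.n_cols;
  const int d = Z.n_cols;
  const double scl = 1.0 / std::sqrt((double)da);
  arma::mat Q = Z * Wq, K = Z * Wk, V = Z * Wv; // large gemms via BLAS
  arma::mat out(Z.n_rows, d, arma::fill::none);
  arma::cube Acube;
  if (keep_cache) Acube.set_size(P, P, N);
  std::vector<double> Qp(P * da), Kp(P * da), Vp(P * da), A(P * P),
      AV(P * da), orow(P * d);
  for (int p = 0; p < N; ++p) {
    const int r0 = p * P;
    to_rowmajor(Q, r0, P, da, Qp.data());
    to_rowmajor(K, r0, P, da, Kp.data());
    to_rowmajor(V, r0, P, da, Vp.data());
    // A (row-major) = softmax_rows(Qp Kp^T * scl)
    for (int i = 0; i < P; ++i) {
      const double* qi = Qp.data() + i * da;
      double* ai = A.data() + i * P;
      double mx = -1e300;
      for (int j = 0; j < P; ++j) {
        const double* kj = Kp.data() + j * da;
        double s = 0;
        for (int t = 0; t < da; ++t) s += qi[t] * kj[t];
        ai[j] = s * scl;
        mx = std::max(mx, ai[j]);
      }
      double sum = 0;
      for (int j = 0; j < P; ++j) {
        ai[j] = std::exp(ai[j] - mx);
        sum += ai[j];
      }
      for (int j = 0; j < P; ++j) ai[j] /= sum;
    }
    // AV (row-major, P x da) = A * Vp
    std::fill(AV.begin(), AV.end(), 0.0);
    for (int i = 0; i < P; ++i) {
      const double* ai = A.data() + i * P;
      double* avi = AV.data() + i * da;
      for (int j = 0; j < P; ++j) {
        const double aij = ai[j];
        const double* vj = Vp.data() + j * da;
        for (int t = 0; t < da; ++t) avi[t] += aij * vj[t];
      }
    }
    // out rows = AV * Wo
    for (int c = 0; c < d; ++c) {
      const double* wc = Wo.colptr(c);
      for (int i = 0; i < P; ++i) {
        const double* avi = AV.data() + i * da;
        double s = 0;
        for (int t = 0; t < da; ++t) s += avi[t] * wc[t];
        orow[i * d + c] = s;
      }
    }
    from_rowmajor(out, r0, P, d, orow.data());
    if (keep_cache) { // cache stays col-major (P x P symmetric layout swap)
      double* ac = Acube.slice(p).memptr();
      for (int i = 0; i < P; ++i)
        for (int j = 0; j < P; ++j) ac[i + j * P] = A[i * P + j];
    }
  }
  if (keep_cache)
    return List::create(_["out"] = out, _["A"] = Acube, _["Q"] = Q,
                        _["K"] = K, _["V"] = V);
  return List::create(_["out"] = out);
}

// [[Rcpp::export(name = ".cpp_nonlocal_backward")]]
List cpp_nonlocal_backward(const arma::mat& dOut, const arma::mat& Z, int P,
                           const arma::cube& Acube, const arma::mat& Q,
                           const arma::mat& K, const arma::mat& V,
                           const arma::mat& Wq, const arma::mat& Wk,
                           const arma::mat& Wv, const arma::mat& Wo) {
  const int N = Z.n_rows / P;
  const int da = Wq.n_cols;
  const int d = Z.n_cols;
  const double scl = 1.0 / std::sqrt((double)da);
  arma::mat dQ(Z.n_rows, da, arma::fill::none);
  arma::mat dK(Z.n_rows, da, arma::fill::none);
  arma::mat dVm(Z.n_rows, da, arma::fill::none);
  arma::mat dWo(da, d, arma::fill::zeros);
  std::vector<double> Qp(P * da), Kp(P * da), Vp(P * da), dOp(P * d),
      A(P * P), AV(P * da), dAV(P * da), dA(P * P), dS(P * P),
      buf(P * da), buf2(P * da);
  for (int p = 0; p < N; ++p) {
    const int r0 = p * P;
    to_rowmajor(Q, r0, P, da, Qp.data());
    to_rowmajor(K, r0, P, da, Kp.data());
    to_rowmajor(V, r0, P, da, Vp.data());
    to_rowmajor(dOut, r0, P, d, dOp.data());
    { // A row-major from cached col-major slice
      const double* ac = Acube.slice(p).memptr();
      for (int i = 0; i < P; ++i)
        for (int j = 0; j < P; ++j) A[i * P + j] = ac[i + j * P];
    }
    // AV = A * Vp ; dWo += AV^T dOp
    std::fill(AV.begin(), AV.end(), 0.0);
    for (int i = 0; i < P; ++i) {
      const double* ai = A.data() + i * P;
      double* avi = AV.data() + i * da;
      for (int j = 0; j < P; ++j) {
        const double aij = ai[j];
        const double* vj = Vp.data() + j * da;
        for (int t = 0; t < da; ++t) avi[t] += aij * vj[t];
      }
    }
    for (int i = 0; i < P; ++i) {
      const double* avi = AV.data() + i * da;
      const double* doi = dOp.data() + i * d;
      for (int t = 0; t < da; ++t) {
        double* wrow = dWo.memptr() + t; // dWo is da x d, col-major
        const double avit = avi[t];
        for (int c = 0; c < d; ++c) dWo(t, c) += avit * doi[c];
      }
    }
    // dAV = dOp * Wo^T (row-major P x da)
    for (int i = 0; i < P; ++i) {
      const double* doi = dOp.data() + i * d;
      double* davi = dAV.data() + i * da;
      for (int t = 0; t < da; ++t) {
        const double* wc = Wo.memptr() + t; // Wo(t, c) stride da
        double s = 0;
        for (int c = 0; c < d; ++c) s += doi[c] * Wo(t, c);
        davi[t] = s;
      }
    }
    // dA = dAV Vp^T ; dV = A^T dAV
    for (int i = 0; i < P; ++i) {
      const double* davi = dAV.data() + i * da;
      double* dai = dA.data() + i * P;
      for (int j = 0; j < P; ++j) {
        const double* vj = Vp.data() + j * da;
        double s = 0;
        for (int t = 0; t < da; ++t) s += davi[t] * vj[t];
        dai[j] = s;
      }
    }
    std::fill(buf.begin(), buf.end(), 0.0); // buf = dV row-major
    for (int i = 0; i < P; ++i) {
      const double* ai = A.data() + i * P;
      const double* davi = dAV.data() + i * da;
      for (int j = 0; j < P; ++j) {
        const double aij = ai[j];
        double* dvj = buf.data() + j * da;
        for (int t = 0; t < da; ++t) dvj[t] += aij * davi[t];
      }
    }
    from_rowmajor(dVm, r0, P, da, buf.data());
    // softmax backward per row: dS = (dA - rowdot(dA, A)) * A
    for (int i = 0; i < P; ++i) {
      const double* ai = A.data() + i * P;
      const double* dai = dA.data() + i * P;
      double* dsi = dS.data() + i * P;
      double dot = 0;
      for (int j = 0; j < P; ++j) dot += dai[j] * ai[j];
      for (int j = 0; j < P; ++j) dsi[j] = (dai[j] - dot) * ai[j];
    }
    // dQ = dS Kp scl ; dK = dS^T Qp scl
    std::fill(buf.begin(), buf.end(), 0.0);
    std::fill(buf2.begin(), buf2.end(), 0.0);
    for (int i = 0; i < P; ++i) {
      const double* dsi = dS.data() + i * P;
      double* dqi = buf.data() + i * da;
      const double* qi = Qp.data() + i * da;
      for (int j = 0; j < P; ++j) {
        const double sij = dsi[j];
        const double* kj = Kp.data() + j * da;
        double* dkj = buf2.data() + j * da;
        for (int t = 0; t < da; ++t) {
          dqi[t] += sij * kj[t];
          dkj[t] += sij * qi[t];
        }
      }
    }
    for (int i = 0; i < P * da; ++i) { buf[i] *= scl; buf2[i] *= scl; }
    from_rowmajor(dQ, r0, P, da, buf.data());
    from_rowmajor(dK, r0, P, da, buf2.data());
  }
  arma::mat dZ = dQ * Wq.t() + dK * Wk.t() + dVm * Wv.t();
  arma::mat dWq = Z.t() * dQ, dWk = Z.t() * dK, dWv = Z.t() * dVm;
  return List::create(_["dZ"] = dZ, _["dWq"] = dWq, _["dWk"] = dWk,
                      _["dWv"] = dWv, _["dWo"] = dWo);
}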