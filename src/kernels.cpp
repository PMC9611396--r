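// Recurrent compute kernels.
//
// A recurrent factor is an LSTM unrolled over the full sequence (no
// truncation) with an optional linear output projection z_t = h_t Wz + bz
// and an optional elementwise activation on z. Gate order in the fused
// weight matrices is (input, forget, cell, output): Wx is in x 4h, Wh is
// h x 4h, b is 1 x 4h. All sequences are row-per-frame matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline mat act_apply(const mat& x, int act) {
  if (act == 1) return clamp(x, 0.0, datum::inf); // ReLU
  if (act == 2) return tanh(x);
  return x;
}

// derivative of activation given pre-activation input
static inline mat act_deriv(const mat& pre, int act) {
  if (act == 1) return conv_to<mat>::from(pre > 0.0);
  if (act == 2) { mat t = tanh(pre); return 1.0 - t % t; }
  return ones<mat>(pre.n_rows, pre.n_cols);
}

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::rowvec& b,
                      const arma::mat& Wz, const arma::rowvec& bz,
                      bool project, int act) {
  const uword T = X.n_rows;
  const uword h = Wh.n_rows;

  mat H(T, h), Cc(T, h), TC(T, h), G(T, 4 * h); // post-activation gates
  rowvec hprev(h, fill::zeros), cprev(h, fill::zeros);
  rowvec a(4 * h);

  // pre-compute all input contributions in one GEMM
  mat A = X * Wx;
  A.each_row() += b;

  for (uword t = 0; t < T; ++t) {
    a = A.row(t);
    a += hprev * Wh;
    const double* pa = a.memptr();
    for (uword j = 0; j < h; ++j) {
      double gi = 1.0 / (1.0 + std::exp(-pa[j]));
      double gf = 1.0 / (1.0 + std::exp(-pa[h + j]));
      double gg = std::tanh(pa[2 * h + j]);
      double go = 1.0 / (1.0 + std::exp(-pa[3 * h + j]));
      double c = gf * cprev(j) + gi * gg;
      G(t, j) = gi;
      G(t, h + j) = gf;
      G(t, 2 * h + j) = gg;
      G(t, 3 * h + j) = go;
      Cc(t, j) = c;
      cprev(j) = c;
      double tc = std::tanh(c);
      TC(t, j) = tc;
      double hh = go * tc;
      H(t, j) = hh;
      hprev(j) = hh;
    }
  }

  List out = List::create(_["H"] = H, _["C"] = Cc, _["TC"] = TC,
                          _["G"] = G);
  if (project) {
    mat Zpre = H * Wz;
    Zpre.each_row() += bz;
    out["Zpre"] = Zpre;
    out["Z"] = act_apply(Zpre, act);
  } else {
    out["Z"] = H;
  }
  return out;
}

// Backpropagation through time. dZ is the gradient w.r.t. the factor
// output Z (same shape). Returns gradients for every parameter and dX.
// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::mat& Wz,
                       const arma::mat& H, const arma::mat& Cc,
                       const arma::mat& TC, const arma::mat& G,
                       const arma::mat& Zpre,
                       const arma::mat& dZ, bool project, int act,
                       bool need_dx) {
  const uword T = X.n_rows;
  const uword h = Wh.n_rows;

  mat dWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat dWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  rowvec db(4 * h, fill::zeros);

  mat dH(T, h, fill::zeros);
  mat dWz, dZpre;
  rowvec dbz;
  if (project) {
    dZpre = dZ % act_deriv(Zpre, act);
    dWz = H.t() * dZpre;
    dbz = sum(dZpre, 0);
    dH = dZpre * Wz.t();
  } else {
    dH = dZ;
  }

  rowvec dhnext(h, fill::zeros), dcnext(h, fill::zeros);
  rowvec da(4 * h);
  mat dA(T, 4 * h); // gradient at pre-activation gates, filled backwards

  for (uword tt = T; tt-- > 0;) {
    for (uword j = 0; j < h; ++j) {
      double dh = dH(tt, j) + dhnext(j);
      double gi = G(tt, j);
      double gf = G(tt, h + j);
      double gg = G(tt, 2 * h + j);
      double go = G(tt, 3 * h + j);
      double tc = TC(tt, j);
      double dc = dcnext(j) + dh * go * (1.0 - tc * tc);
      double cprev = (tt == 0) ? 0.0 : Cc(tt - 1, j);
      da(j) = dc * gg * gi * (1.0 - gi);
      da(h + j) = dc * cprev * gf * (1.0 - gf);
      da(2 * h + j) = dc * gi * (1.0 - gg * gg);
      da(3 * h + j) = dh * tc * go * (1.0 - go);
      dcnext(j) = dc * gf;
    }
    dA.row(tt) = da;
    if (tt > 0) {
      dhnext = da * Wh.t();
    } else {
      dhnext.zeros();
    }
  }

  // recurrent-kernel gradient in one GEMM over the shifted hidden states
  if (T > 1) {
    dWh = H.rows(0, T - 2).t() * dA.rows(1, T - 1);
  }
  dWx = X.t() * dA;
  db = sum(dA, 0);

  List out = List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db);
  if (need_dx) out["dX"] = dA * Wx.t();
  if (project) {
    out["dWz"] = dWz;
    out["dbz"] = dbz;
  }
  return out;
}

// In-place Adam update over parallel lists of parameter/gradient/moment
// arrays. Mutates params, m and v directly (they are owned by the factor
// environments and never shared outside the package).
// [[Rcpp::export(name = ".adam_step_cpp")]]
void adam_step_cpp(List params, List grads, List m, List v, double lr,
                   double t, double beta1, double beta2, double eps) {
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t k = 0; k < params.size(); ++k) {
    NumericVector p = params[k], g = grads[k], mm = m[k], vv = v[k];
    const R_xlen_t n = p.size();
    double* pp = REAL(p);
    double* pg = REAL(g);
    double* pm = REAL(mm);
    double* pv = REAL(vv);
    for (R_xlen_t i = 0; i < n; ++i) {
      pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
      pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
      pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
    }
  }
}

// zero a list of gradient accumulators in place
// [[Rcpp::export(name = ".zero_arrays_cpp")]]
void zero_arrays_cpp(List grads) {
  for (R_xlen_t k = 0; k < grads.size(); ++k) {
    NumericVector g = grads[k];
    std::fill(REAL(g), REAL(g) + g.size(), 0.0);
  }
}

// dst += src, in place (gradient accumulation without allocation)
// [[Rcpp::export(name = ".accum_cpp")]]
void accum_cpp(NumericVector dst, NumericVector src) {
  const R_xlen_t n = dst.size();
  if (src.size() != n) stop("gradient shape mismatch");
  double* pd = REAL(dst);
  const double* ps = REAL(src);
  for (R_xlen_t i = 0; i < n; ++i) pd[i] += ps[i];
}
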