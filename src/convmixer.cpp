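// Core numerics: direct-form-II-transposed IIR filtering (zero-phase filter
// support) and the 1-D ConvMixer forward/backward passes.
//
// Activation layout: windows are stacked row-wise, so an activation is an
// (B * Lp) x H matrix whose rows are ordered window-major (all positions of
// window 0, then window 1, ...). Batchnorm statistics are per channel
// (column) over all rows; the depthwise convolution never crosses a window
// boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector iir_df2t(Rcpp::NumericVector b, Rcpp::NumericVector a,
                             Rcpp::NumericVector x, Rcpp::NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nord = std::max(nb, na) - 1;
  std::vector<double> bb(nord + 1, 0.0), aa(nord + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const double a0 = aa[0];
  for (int i = 0; i <= nord; ++i) { bb[i] /= a0; aa[i] /= a0; }
  std::vector<double> z(nord, 0.0);
  for (int i = 0; i < (int)zi.size() && i < nord; ++i) z[i] = zi[i];
  Rcpp::NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nord > 0 ? z[0] : 0.0);
    for (int j = 0; j < nord - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nord > 0) z[nord - 1] = bb[nord] * xi - aa[nord] * yi;
    y[i] = yi;
  }
  return y;
}

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

// y = z * Phi(z); Phi (the standard normal CDF) is cached for the backward
static mat gelu(const mat& z, mat& Phi) {
  Phi.set_size(z.n_rows, z.n_cols);
  mat out(z.n_rows, z.n_cols);
  const double* zp = z.memptr();
  double* pp = Phi.memptr();
  double* op = out.memptr();
  const uword n = z.n_elem;
  for (uword i = 0; i < n; ++i) {
    pp[i] = 0.5 * (1.0 + std::erf(zp[i] * INV_SQRT2));
    op[i] = zp[i] * pp[i];
  }
  return out;
}

static mat gelu(const mat& z) {
  mat Phi;
  return gelu(z, Phi);
}

// d/dz = Phi(z) + z * phi(z), with Phi cached from the forward pass
static mat gelu_grad(const mat& z, const mat& Phi) {
  mat out(z.n_rows, z.n_cols);
  const double* zp = z.memptr();
  const double* pp = Phi.memptr();
  double* op = out.memptr();
  const uword n = z.n_elem;
  for (uword i = 0; i < n; ++i)
    op[i] = pp[i] + zp[i] * INV_SQRT2PI * std::exp(-0.5 * zp[i] * zp[i]);
  return out;
}

struct BnCache { rowvec mu, var, istd; mat xhat; };

// training-mode batchnorm (biased variance, per column)
static mat bn_forward(const mat& x, const rowvec& g, const rowvec& b,
                      double eps, BnCache& c) {
  c.mu = mean(x, 0);
  mat centered = x.each_row() - c.mu;
  c.var = mean(square(centered), 0);
  c.istd = 1.0 / sqrt(c.var + eps);
  c.xhat = centered.each_row() % c.istd;
  mat y = c.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat bn_backward(const mat& dy, const BnCache& c, const rowvec& g,
                       rowvec& dg, rowvec& db) {
  const double n = (double)dy.n_rows;
  dg = sum(dy % c.xhat, 0);
  db = sum(dy, 0);
  mat dxhat = dy.each_row() % g;
  rowvec s1 = sum(dxhat, 0) / n;
  rowvec s2 = sum(dxhat % c.xhat, 0) / n;
  mat dx = dxhat;
  dx.each_row() -= s1;
  dx -= c.xhat.each_row() % s2;
  dx.each_row() %= c.istd;
  return dx;
}

static mat bn_infer(const mat& x, const rowvec& g, const rowvec& b,
                    const rowvec& rm, const rowvec& rv, double eps) {
  mat y = x.each_row() - rm;
  y.each_row() %= (g / sqrt(rv + eps));
  y.each_row() += b;
  return y;
}

// depthwise convolution, 'same' zero padding, within-window only.
// Shifts are applied globally over the stacked (B*Lp) x H activation and the
// few rows per window that would borrow from a neighbouring window are then
// corrected, which avoids per-window small-matrix operations.

// out[p] += w_j .* in[p + off] for positions valid within each window;
// the shift runs over the whole stacked activation and the few rows per
// window that crossed a window boundary are then corrected
static void add_shifted(mat& out, const mat& in_c, const rowvec& wj, int off,
                        int B, int Lp) {
  mat& in = const_cast<mat&>(in_c);  // read-only use; enables fused each_row
  const int n = B * Lp;
  if (off == 0) { out += in.each_row() % wj; return; }
  if (off > 0) {
    out.rows(0, n - 1 - off) += in.rows(off, n - 1).each_row() % wj;
    for (int b = 0; b + 1 < B; ++b) {
      const int tail = (b + 1) * Lp - off;
      out.rows(tail, tail + off - 1) -=
        in.rows((b + 1) * Lp, (b + 1) * Lp + off - 1).each_row() % wj;
    }
  } else {
    const int o = -off;
    out.rows(o, n - 1) += in.rows(0, n - 1 - o).each_row() % wj;
    for (int b = 1; b < B; ++b) {
      out.rows(b * Lp, b * Lp + o - 1) -=
        in.rows(b * Lp - o, b * Lp - 1).each_row() % wj;
    }
  }
}

// per-channel sum of dout[p] .* in[p + off] over within-window positions
static rowvec corr_shifted(const mat& dout, const mat& in, int off,
                           int B, int Lp) {
  const int n = B * Lp;
  rowvec s(in.n_cols, fill::zeros);
  if (off == 0) return sum(dout % in, 0);
  if (off > 0) {
    s = sum(dout.rows(0, n - 1 - off) % in.rows(off, n - 1), 0);
    for (int b = 0; b + 1 < B; ++b) {
      const int tail = (b + 1) * Lp - off;
      s -= sum(dout.rows(tail, tail + off - 1) %
               in.rows((b + 1) * Lp, (b + 1) * Lp + off - 1), 0);
    }
  } else {
    const int o = -off;
    s = sum(dout.rows(o, n - 1) % in.rows(0, n - 1 - o), 0);
    for (int b = 1; b < B; ++b) {
      s -= sum(dout.rows(b * Lp, b * Lp + o - 1) %
               in.rows(b * Lp - o, b * Lp - 1), 0);
    }
  }
  return s;
}

static mat dw_conv(const mat& in, const mat& w, const rowvec& b,
                   int B, int Lp) {
  const int k = w.n_rows, c = (k - 1) / 2;
  mat out(in.n_rows, in.n_cols, fill::zeros);
  for (int j = 0; j < k; ++j)
    add_shifted(out, in, w.row(j), j - c, B, Lp);
  out.each_row() += b;
  return out;
}

static void dw_conv_backward(const mat& dout, const mat& in, const mat& w,
                             int B, int Lp, mat& din_acc, mat& dw, rowvec& db) {
  const int k = w.n_rows, c = (k - 1) / 2;
  dw.zeros(k, w.n_cols);
  db = sum(dout, 0);
  for (int j = 0; j < k; ++j) {
    const int off = j - c;
    // din[p + off] += w_j .* dout[p]  <=>  shifted add with offset -off
    add_shifted(din_acc, dout, w.row(j), -off, B, Lp);
    dw.row(j) = corr_shifted(dout, in, off, B, Lp);
  }
}

// patch embedding input: rows are (window, token), columns the P raw samples
static mat make_patches(const mat& X, int P, int Lp) {
  const int B = X.n_rows;
  mat M(B * Lp, P);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lp; ++t)
      for (int p = 0; p < P; ++p)
        M(b * Lp + t, p) = X(b, t * P + p);
  return M;
}

static mat pool_mean(const mat& a, int B, int Lp) {
  mat pooled(B, a.n_cols);
  for (int b = 0; b < B; ++b)
    pooled.row(b) = mean(a.rows(b * Lp, (b + 1) * Lp - 1), 0);
  return pooled;
}

// forward + backward + MSE loss; returns grads and batch BN statistics
// [[Rcpp::export]]
Rcpp::List cm_grad_cpp(Rcpp::List params, const arma::mat& X,
                       const arma::vec& y, int P, int kernel, int H,
                       int depth, double eps) {
  const int B = X.n_rows, L = X.n_cols, Lp = L / P;
  Rcpp::List grads, bstats;

  mat M = make_patches(X, P, Lp);
  mat Wp = Rcpp::as<mat>(params["patch_w"]);
  rowvec bp = Rcpp::as<rowvec>(params["patch_b"]);
  mat Z0 = M * Wp;
  Z0.each_row() += bp;
  mat Phi0;
  mat G0 = gelu(Z0, Phi0);
  BnCache c0;
  rowvec g0 = Rcpp::as<rowvec>(params["bn0_g"]);
  mat A = bn_forward(G0, g0, Rcpp::as<rowvec>(params["bn0_b"]), eps, c0);
  bstats["bn0_m"] = c0.mu; bstats["bn0_v"] = c0.var;

  std::vector<mat> Ain(depth), Z1(depth), Z2(depth), Rres(depth);
  std::vector<mat> Phi1(depth), Phi2(depth);
  std::vector<BnCache> c1(depth), c2(depth);
  for (int i = 0; i < depth; ++i) {
    const std::string s = std::to_string(i + 1);
    Ain[i] = A;
    mat wdw = Rcpp::as<mat>(params["dw" + s + "_w"]);
    Z1[i] = dw_conv(A, wdw, Rcpp::as<rowvec>(params["dw" + s + "_b"]), B, Lp);
    mat G1 = gelu(Z1[i], Phi1[i]);
    mat B1 = bn_forward(G1, Rcpp::as<rowvec>(params["bn" + s + "a_g"]),
                        Rcpp::as<rowvec>(params["bn" + s + "a_b"]), eps, c1[i]);
    bstats["bn" + s + "a_m"] = c1[i].mu; bstats["bn" + s + "a_v"] = c1[i].var;
    Rres[i] = Ain[i] + B1;
    mat Wpw = Rcpp::as<mat>(params["pw" + s + "_w"]);
    Z2[i] = Rres[i] * Wpw;
    Z2[i].each_row() += Rcpp::as<rowvec>(params["pw" + s + "_b"]);
    mat G2 = gelu(Z2[i], Phi2[i]);
    A = bn_forward(G2, Rcpp::as<rowvec>(params["bn" + s + "b_g"]),
                   Rcpp::as<rowvec>(params["bn" + s + "b_b"]), eps, c2[i]);
    bstats["bn" + s + "b_m"] = c2[i].mu; bstats["bn" + s + "b_v"] = c2[i].var;
  }

  mat pooled = pool_mean(A, B, Lp);
  vec head_w = Rcpp::as<vec>(params["head_w"]);
  double head_b = Rcpp::as<double>(params["head_b"]);
  vec pred = pooled * head_w + head_b;

  vec err = pred - y;
  double loss = dot(err, err) / B;
  vec dpred = 2.0 * err / B;

  grads["head_w"] = vec(pooled.t() * dpred);
  grads["head_b"] = accu(dpred);
  mat dpooled = dpred * head_w.t();          // B x H
  mat dA(B * Lp, H);
  for (int b = 0; b < B; ++b)
    dA.rows(b * Lp, (b + 1) * Lp - 1) = repmat(dpooled.row(b) / Lp, Lp, 1);

  for (int i = depth - 1; i >= 0; --i) {
    const std::string s = std::to_string(i + 1);
    rowvec dg, db;
    mat dG2 = bn_backward(dA, c2[i], Rcpp::as<rowvec>(params["bn" + s + "b_g"]),
                          dg, db);
    grads["bn" + s + "b_g"] = dg; grads["bn" + s + "b_b"] = db;
    mat dZ2 = dG2 % gelu_grad(Z2[i], Phi2[i]);
    mat Wpw = Rcpp::as<mat>(params["pw" + s + "_w"]);
    grads["pw" + s + "_w"] = mat(Rres[i].t() * dZ2);
    grads["pw" + s + "_b"] = rowvec(sum(dZ2, 0));
    mat dR = dZ2 * Wpw.t();
    // residual: gradient reaches the block input both directly and through
    // the depthwise branch
    mat dAin = dR;
    mat dG1 = bn_backward(dR, c1[i], Rcpp::as<rowvec>(params["bn" + s + "a_g"]),
                          dg, db);
    grads["bn" + s + "a_g"] = dg; grads["bn" + s + "a_b"] = db;
    mat dZ1 = dG1 % gelu_grad(Z1[i], Phi1[i]);
    mat wdw = Rcpp::as<mat>(params["dw" + s + "_w"]);
    mat dwdw; rowvec dbdw;
    dw_conv_backward(dZ1, Ain[i], wdw, B, Lp, dAin, dwdw, dbdw);
    grads["dw" + s + "_w"] = dwdw;
    grads["dw" + s + "_b"] = dbdw;
    dA = dAin;
  }

  rowvec dg0, db0;
  mat dG0 = bn_backward(dA, c0, g0, dg0, db0);
  grads["bn0_g"] = dg0; grads["bn0_b"] = db0;
  mat dZ0 = dG0 % gelu_grad(Z0, Phi0);
  grads["patch_w"] = mat(M.t() * dZ0);
  grads["patch_b"] = rowvec(sum(dZ0, 0));

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("pred") = pred,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("bstats") = bstats);
}

// inference-mode forward pass (frozen running statistics)
// [[Rcpp::export]]
arma::vec cm_predict_cpp(Rcpp::List params, Rcpp::List rstats,
                         const arma::mat& X, int P, int kernel, int H,
                         int depth, double eps) {
  const int B = X.n_rows, L = X.n_cols, Lp = L / P;
  mat M = make_patches(X, P, Lp);
  mat Z0 = M * Rcpp::as<mat>(params["patch_w"]);
  Z0.each_row() += Rcpp::as<rowvec>(params["patch_b"]);
  mat A = bn_infer(gelu(Z0), Rcpp::as<rowvec>(params["bn0_g"]),
                   Rcpp::as<rowvec>(params["bn0_b"]),
                   Rcpp::as<rowvec>(rstats["bn0_m"]),
                   Rcpp::as<rowvec>(rstats["bn0_v"]), eps);
  for (int i = 0; i < depth; ++i) {
    const std::string s = std::to_string(i + 1);
    mat Z1 = dw_conv(A, Rcpp::as<mat>(params["dw" + s + "_w"]),
                     Rcpp::as<rowvec>(params["dw" + s + "_b"]), B, Lp);
    mat B1 = bn_infer(gelu(Z1), Rcpp::as<rowvec>(params["bn" + s + "a_g"]),
                      Rcpp::as<rowvec>(params["bn" + s + "a_b"]),
                      Rcpp::as<rowvec>(rstats["bn" + s + "a_m"]),
                      Rcpp::as<rowvec>(rstats["bn" + s + "a_v"]), eps);
    mat Rres = A + B1;
    mat Z2 = Rres * Rcpp::as<mat>(params["pw" + s + "_w"]);
    Z2.each_row() += Rcpp::as<rowvec>(params["pw" + s + "_b"]);
    A = bn_infer(gelu(Z2), Rcpp::as<rowvec>(params["bn" + s + "b_g"]),
                 Rcpp::as<rowvec>(params["bn" + s + "b_b"]),
                 Rcpp::as<rowvec>(rstats["bn" + s + "b_m"]),
                 Rcpp::as<rowvec>(rstats["bn" + s + "b_v"]), eps);
  }
  mat pooled = pool_mean(A, B, Lp);
  return pooled * Rcpp::as<vec>(params["head_w"]) +
         Rcpp::as<double>(params["head_b"]);
}

// ADMM inner loop of variational mode decomposition, on the fftshift'ed
// positive-half spectrum. Mirrors the R-side setup in vmd_decompose().
// [[Rcpp::export]]
Rcpp::List vmd_admm_cpp(const arma::cx_vec& f_hat_plus,
                        const arma::vec& freqs, const arma::vec& omega_init,
                        double alpha, double tau, double tol, int max_iter) {
  const int T = f_hat_plus.n_elem, K = omega_init.n_elem;
  const int p0 = T / 2;                       // first non-negative bin
  vec omega = omega_init;
  cx_mat u_hat(T, K, fill::zeros), u_prev(T, K, fill::zeros);
  cx_vec lambda_hat(T, fill::zeros);
  cx_vec sum_uk(T, fill::zeros);
  const vec fpos = freqs.subvec(p0, T - 1);
  int n_iter = 0;
  while (true) {
    ++n_iter;
    u_prev = u_hat;
    for (int k = 0; k < K; ++k) {
      sum_uk -= u_hat.col(k);
      u_hat.col(k) = (f_hat_plus - sum_uk - lambda_hat / 2.0) /
        (1.0 + 2.0 * alpha * square(freqs - omega(k)));
      vec pw = square(abs(u_hat.col(k).subvec(p0, T - 1)));
      double tot = accu(pw);
      if (tot > 0) omega(k) = dot(fpos, pw) / tot;
      sum_uk += u_hat.col(k);
    }
    if (tau > 0) lambda_hat += tau * (sum_uk - f_hat_plus);
    double num_d = accu(square(abs(u_hat - u_prev)));
    double den_d = accu(square(abs(u_prev)));
    double rel = den_d > 0 ? num_d / den_d : num_d;
    if (rel < tol || n_iter >= max_iter) break;
  }
  return Rcpp::List::create(Rcpp::Named("u_hat") = u_hat,
                            Rcpp::Named("omega") = omega,
                            Rcpp::Named("n_iter") = n_iter);
}
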