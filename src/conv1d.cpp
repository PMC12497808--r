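// Grouped, dilated 1-D convolution (cross-correlation, the deep-learning
// convention) with asymmetric zero padding, plus its gradients.
//
// Layouts (match R arrays column-major):
//   x  : cube (in_ch,  L_in,  batch)
//   w  : cube (out_ch, in_ch/groups, k)
//   y  : cube (out_ch, L_out, batch),  L_out = L_in + pad_l + pad_r - dil*(k-1)
//
// All batch slices are lowered into one im2col matrix per group so each
// group costs a single BLAS gemm; that keeps the CPU training loop fast.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// im2col over the whole batch for one channel group:
// out (in_pg*k, L_out*batch); column s*L_out + t holds the receptive field
// of output step t in slice s
static void im2col_all(const cube& x, int k, int dil, int pad_l,
                       int c0, int in_pg, int L_out, mat& out) {
  const int L_in = x.n_cols, batch = x.n_slices;
  for (int s = 0; s < batch; ++s)
    for (int t = 0; t < L_out; ++t) {
      double* col = out.colptr((std::size_t)s * L_out + t);
      for (int c = 0; c < in_pg; ++c)
        for (int kk = 0; kk < k; ++kk) {
          const int src = t + kk * dil - pad_l;
          col[c * k + kk] =
            (src >= 0 && src < L_in) ? x(c0 + c, src, s) : 0.0;
        }
    }
}

static mat group_weight(const cube& w, int g, int out_pg, int in_pg, int k) {
  mat W(out_pg, in_pg * k);
  for (int o = 0; o < out_pg; ++o)
    for (int c = 0; c < in_pg; ++c)
      for (int kk = 0; kk < k; ++kk)
        W(o, c * k + kk) = w(g * out_pg + o, c, kk);
  return W;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::vec& b, int pad_l, int pad_r,
                          int dil, int groups, bool has_bias) {
  const int L_in = x.n_cols, batch = x.n_slices;
  const int out_ch = w.n_rows, in_pg = w.n_cols, k = w.n_slices;
  const int out_pg = out_ch / groups;
  const int L_out = L_in + pad_l + pad_r - dil * (k - 1);

  cube y(out_ch, L_out, batch);
  mat xcol(in_pg * k, (std::size_t)L_out * batch);
  for (int g = 0; g < groups; ++g) {
    im2col_all(x, k, dil, pad_l, g * in_pg, in_pg, L_out, xcol);
    mat Y = group_weight(w, g, out_pg, in_pg, k) * xcol;
    if (has_bias)
      Y.each_col() += b.subvec(g * out_pg, (g + 1) * out_pg - 1);
    for (int s = 0; s < batch; ++s)
      y.slice(s).rows(g * out_pg, (g + 1) * out_pg - 1) =
        Y.cols((std::size_t)s * L_out, (std::size_t)(s + 1) * L_out - 1);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::cube& dy, int pad_l, int pad_r,
                          int dil, int groups, bool has_bias) {
  const int in_ch = x.n_rows, L_in = x.n_cols, batch = x.n_slices;
  const int out_ch = w.n_rows, in_pg = w.n_cols, k = w.n_slices;
  const int out_pg = out_ch / groups;
  const int L_out = dy.n_cols;

  cube dx(in_ch, L_in, batch, fill::zeros);
  cube dw(out_ch, in_pg, k);
  vec db(out_ch, fill::zeros);
  mat xcol(in_pg * k, (std::size_t)L_out * batch);
  mat dY(out_pg, (std::size_t)L_out * batch);
  for (int g = 0; g < groups; ++g) {
    for (int s = 0; s < batch; ++s)
      dY.cols((std::size_t)s * L_out, (std::size_t)(s + 1) * L_out - 1) =
        dy.slice(s).rows(g * out_pg, (g + 1) * out_pg - 1);
    im2col_all(x, k, dil, pad_l, g * in_pg, in_pg, L_out, xcol);
    mat dWg = dY * xcol.t();                      // (out_pg, in_pg*k)
    for (int o = 0; o < out_pg; ++o)
      for (int c = 0; c < in_pg; ++c)
        for (int kk = 0; kk < k; ++kk)
          dw(g * out_pg + o, c, kk) = dWg(o, c * k + kk);
    mat dXcol = group_weight(w, g, out_pg, in_pg, k).t() * dY;
    for (int s = 0; s < batch; ++s)
      for (int t = 0; t < L_out; ++t) {
        const double* col = dXcol.colptr((std::size_t)s * L_out + t);
        for (int c = 0; c < in_pg; ++c)
          for (int kk = 0; kk < k; ++kk) {
            const int src = t + kk * dil - pad_l;
            if (src >= 0 && src < L_in)
              dx(g * in_pg + c, src, s) += col[c * k + kk];
          }
      }
    if (has_bias)
      db.subvec(g * out_pg, (g + 1) * out_pg - 1) = sum(dY, 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
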