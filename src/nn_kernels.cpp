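// Compiled kernels for the sequence models.
//
// Activations are (B*L) x d matrices with row index r = b + B*t (batch
// fastest), so all rows of one position block are contiguous and a shift
// along the position axis is a contiguous row-block copy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -1e30;

// Y = M W + bias (broadcast over rows)
// [[Rcpp::export(name = ".nn_linear")]]
arma::mat nn_linear(const arma::mat& M, const arma::mat& W,
                    const arma::rowvec& bias) {
  arma::mat Y = M * W;
  Y.each_row() += bias;
  return Y;
}

// row-wise softmax
// [[Rcpp::export(name = ".nn_softmax_rows")]]
arma::mat nn_softmax_rows(const arma::mat& M) {
  arma::mat P = M;
  P.each_col() -= arma::max(P, 1);
  P = arma::exp(P);
  P.each_col() /= arma::sum(P, 1);
  return P;
}

// 1-D convolution along positions: U is a (d_in, d_out, k) cube, symmetric
// zero padding of (k-1)/2, stride 1.
// [[Rcpp::export(name = ".nn_conv_fwd")]]
arma::mat nn_conv_fwd(const arma::mat& X, const arma::cube& U,
                      const arma::rowvec& bias, int B, int L) {
  const int k = U.n_slices, half = (k - 1) / 2;
  arma::mat Y(X.n_rows, U.n_cols, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int o = j - half;                 // out position t reads input t+o
    const int t0 = std::max(0, -o), t1 = L - 1 - std::max(0, o);
    if (t0 > t1) continue;
    Y.rows(B * t0, B * t1 + B - 1) +=
      X.rows(B * (t0 + o), B * (t1 + o) + B - 1) * U.slice(j);
  }
  Y.each_row() += bias;
  return Y;
}

// [[Rcpp::export(name = ".nn_conv_bwd")]]
List nn_conv_bwd(const arma::mat& dY, const arma::mat& X, const arma::cube& U,
                 int B, int L) {
  const int k = U.n_slices, half = (k - 1) / 2;
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::cube dU(U.n_rows, U.n_cols, k, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int o = j - half;
    const int t0 = std::max(0, -o), t1 = L - 1 - std::max(0, o);
    if (t0 > t1) continue;
    const arma::mat dYb = dY.rows(B * t0, B * t1 + B - 1);
    dX.rows(B * (t0 + o), B * (t1 + o) + B - 1) += dYb * U.slice(j).t();
    dU.slice(j) = X.rows(B * (t0 + o), B * (t1 + o) + B - 1).t() * dYb;
  }
  return List::create(_["dX"] = dX, _["dU"] = dU,
                      _["db"] = arma::sum(dY, 0));
}

// layer normalization over the feature axis
// [[Rcpp::export(name = ".nn_ln_fwd")]]
List nn_ln_fwd(const arma::mat& M, const arma::rowvec& g,
               const arma::rowvec& b, double eps) {
  arma::vec mu = arma::mean(M, 1);
  arma::mat xc = M.each_col() - mu;
  arma::vec inv = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + eps);
  arma::mat xhat = xc.each_col() % inv;
  arma::mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return List::create(_["out"] = Y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = ".nn_ln_bwd")]]
List nn_ln_bwd(const arma::mat& dY, const arma::mat& xhat,
               const arma::vec& inv, const arma::rowvec& g) {
  arma::mat dxhat = dY.each_row() % g;
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  return List::create(_["dX"] = dX,
                      _["dg"] = arma::sum(dY % xhat, 0),
                      _["db"] = arma::sum(dY, 0));
}

// Multi-head scaled-dot-product attention on flat (B*L) x d matrices.
// key_mask: B x L (1 = attend). Returns O and the attention weights
// cube A (L x L x B*H), slice h*B + b.
// [[Rcpp::export(name = ".nn_attn_fwd")]]
List nn_attn_fwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 const arma::mat& key_mask, int B, int L, int H,
                 bool causal, double scale) {
  const int d = Q.n_cols, dh = d / H;
  arma::mat O(Q.n_rows, d, arma::fill::zeros);
  arma::cube A(L, L, B * H);
  arma::uvec rows(L);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < L; ++t) rows(t) = b + B * t;
    for (int h = 0; h < H; ++h) {
      const arma::span cols(h * dh, (h + 1) * dh - 1);
      arma::mat Qs = Q.submat(rows, arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1));
      arma::mat Ks = K.submat(rows, arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1));
      arma::mat Vs = V.submat(rows, arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1));
      arma::mat S = Qs * Ks.t() * scale;
      for (int j = 0; j < L; ++j)
        if (key_mask(b, j) == 0.0) S.col(j).fill(NEG_INF);
      if (causal)
        for (int i = 0; i < L; ++i)
          for (int j = i + 1; j < L; ++j) S(i, j) = NEG_INF;
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      A.slice(h * B + b) = S;
      O.submat(rows, arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1)) = S * Vs;
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export(name = ".nn_attn_bwd")]]
List nn_attn_bwd(const arma::mat& dO, const arma::cube& A, const arma::mat& Q,
                 const arma::mat& K, const arma::mat& V, int B, int L, int H,
                 double scale) {
  const int d = Q.n_cols, dh = d / H;
  arma::mat dQ(Q.n_rows, d, arma::fill::zeros), dK = dQ, dV = dQ;
  arma::uvec rows(L);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < L; ++t) rows(t) = b + B * t;
    for (int h = 0; h < H; ++h) {
      arma::uvec cols = arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1);
      arma::mat Qs = Q.submat(rows, cols);
      arma::mat Ks = K.submat(rows, cols);
      arma::mat Vs = V.submat(rows, cols);
      arma::mat dOs = dO.submat(rows, cols);
      const arma::mat& As = A.slice(h * B + b);
      arma::mat dA = dOs * Vs.t();
      arma::vec r = arma::sum(dA % As, 1);
      arma::mat dS = As % (dA.each_col() - r);
      dV.submat(rows, cols) = As.t() * dOs;
      dQ.submat(rows, cols) = dS * Ks * scale;
      dK.submat(rows, cols) = dS.t() * Qs * scale;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
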