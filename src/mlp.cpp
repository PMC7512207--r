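#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Single-hidden-layer MLP: logistic hidden units, softmax output,
// cross-entropy error summed over rows plus (decay/2) * ||weights||^2
// (biases unpenalized). Parameter vector layout:
// [W1 (p x h), b1 (h), W2 (h x K), b2 (K)].

static void unpack(const vec& th, int p, int h, int K,
                   mat& W1, rowvec& b1, mat& W2, rowvec& b2) {
  int off = 0;
  W1 = reshape(th.subvec(off, off + p * h - 1), p, h); off += p * h;
  b1 = th.subvec(off, off + h - 1).t();                off += h;
  W2 = reshape(th.subvec(off, off + h * K - 1), h, K); off += h * K;
  b2 = th.subvec(off, off + K - 1).t();
}

static mat forward(const mat& X, const mat& W1, const rowvec& b1,
                   const mat& W2, const rowvec& b2, mat& Z) {
  mat A = X * W1;
  A.each_row() += b1;
  Z = 1.0 / (1.0 + exp(-A));
  mat L = Z * W2;
  L.each_row() += b2;
  L.each_col() -= max(L, 1);           // row-wise stabilization
  mat E = exp(L);
  E.each_col() /= sum(E, 1);
  return E;
}

// [[Rcpp::export]]
double cpp_mlp_obj(const arma::vec& theta, const arma::mat& X,
                   const arma::mat& Y, int h, double decay) {
  const int p = X.n_cols, K = Y.n_cols;
  mat W1, W2, Z;
  rowvec b1, b2;
  unpack(theta, p, h, K, W1, b1, W2, b2);
  mat P = forward(X, W1, b1, W2, b2, Z);
  P.clamp(1e-12, 1.0);
  double ce = -accu(Y % log(P));
  return ce + 0.5 * decay * (accu(W1 % W1) + accu(W2 % W2));
}

// [[Rcpp::export]]
arma::vec cpp_mlp_grad(const arma::vec& theta, const arma::mat& X,
                       const arma::mat& Y, int h, double decay) {
  const int p = X.n_cols, K = Y.n_cols;
  mat W1, W2, Z;
  rowvec b1, b2;
  unpack(theta, p, h, K, W1, b1, W2, b2);
  mat P = forward(X, W1, b1, W2, b2, Z);
  mat dL = P - Y;                                   // n x K
  mat gW2 = Z.t() * dL + decay * W2;
  rowvec gb2 = sum(dL, 0);
  mat dZ = (dL * W2.t()) % Z % (1.0 - Z);           // n x h
  mat gW1 = X.t() * dZ + decay * W1;
  rowvec gb1 = sum(dZ, 0);
  vec g(p * h + h + h * K + K);
  int off = 0;
  g.subvec(off, off + p * h - 1) = vectorise(gW1); off += p * h;
  g.subvec(off, off + h - 1) = gb1.t();            off += h;
  g.subvec(off, off + h * K - 1) = vectorise(gW2); off += h * K;
  g.subvec(off, off + K - 1) = gb2.t();
  return g;
}

// [[Rcpp::export]]
arma::mat cpp_mlp_forward(const arma::mat& X, const arma::mat& W1,
                          const arma::rowvec& b1, const arma::mat& W2,
                          const arma::rowvec& b2) {
  mat Z;
  return forward(X, W1, b1, W2, b2, Z);
}
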