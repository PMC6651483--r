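// Batched LSTM kernels: forward pass and backpropagation through time.
// Inputs are stacked (B*T) x d matrices, rows ordered batch-fastest within
// consecutive time blocks; gate weight matrices are column-stacked in the
// order f, i, o, c. These mirror the scalar gate equations implemented in
// R by lstm_cell_step(), which the test suite uses as the reference.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_layer_forward_cpp(const arma::mat& W, const arma::mat& U,
                                  const arma::vec& b, const arma::mat& xmat,
                                  int B, int T, bool cache) {
  const int h = U.n_rows;
  mat axw = xmat * W;
  axw.each_row() += b.t();
  mat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);
  mat hmat(B * T, h);
  mat F, I, O, G, TC, HP, CP;
  if (cache) {
    F.set_size(B * T, h); I.set_size(B * T, h); O.set_size(B * T, h);
    G.set_size(B * T, h); TC.set_size(B * T, h); HP.set_size(B * T, h);
    CP.set_size(B * T, h);
  }
  for (int t = 0; t < T; t++) {
    const span rows(t * B, t * B + B - 1);
    mat a = axw.rows(rows) + hprev * U;
    mat f = sigm(a.cols(0, h - 1));
    mat i = sigm(a.cols(h, 2 * h - 1));
    mat o = sigm(a.cols(2 * h, 3 * h - 1));
    mat g = tanh(a.cols(3 * h, 4 * h - 1));
    mat cnew = f % cprev + i % g;
    mat tc = tanh(cnew);
    if (cache) {
      F.rows(rows) = f; I.rows(rows) = i; O.rows(rows) = o;
      G.rows(rows) = g; TC.rows(rows) = tc; HP.rows(rows) = hprev;
      CP.rows(rows) = cprev;
    }
    hprev = o % tc;
    hmat.rows(rows) = hprev;
    cprev = cnew;
  }
  if (!cache)
    return Rcpp::List::create(Rcpp::Named("h") = hmat,
                              Rcpp::Named("h_final") = hprev);
  return Rcpp::List::create(
      Rcpp::Named("h") = hmat, Rcpp::Named("h_final") = hprev,
      Rcpp::Named("f") = F, Rcpp::Named("i") = I, Rcpp::Named("o") = O,
      Rcpp::Named("g") = G, Rcpp::Named("tc") = TC, Rcpp::Named("hp") = HP,
      Rcpp::Named("cp") = CP);
}

// [[Rcpp::export]]
Rcpp::List lstm_layer_backward_cpp(const arma::mat& W, const arma::mat& U,
                                   const arma::mat& xmat,
                                   const arma::mat& F, const arma::mat& I,
                                   const arma::mat& O, const arma::mat& G,
                                   const arma::mat& TC, const arma::mat& HP,
                                   const arma::mat& CP,
                                   const arma::mat& dh_final,
                                   const arma::mat& dh_stack,
                                   int B, int T, bool want_dx) {
  const int h = U.n_rows;
  const mat Ut = U.t();
  mat dh_next(B, h, fill::zeros), dc_next(B, h, fill::zeros);
  mat DA(B * T, 4 * h);
  for (int t = T - 1; t >= 0; t--) {
    const span rows(t * B, t * B + B - 1);
    mat dh = dh_next;
    if (dh_stack.n_rows > 0) dh += dh_stack.rows(rows);
    if (t == T - 1 && dh_final.n_rows > 0) dh += dh_final;
    const mat f = F.rows(rows), i = I.rows(rows), o = O.rows(rows);
    const mat g = G.rows(rows), tc = TC.rows(rows), cp = CP.rows(rows);
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat da(B, 4 * h);
    da.cols(0, h - 1) = (dc % cp) % f % (1.0 - f);
    da.cols(h, 2 * h - 1) = (dc % g) % i % (1.0 - i);
    da.cols(2 * h, 3 * h - 1) = (dh % tc) % o % (1.0 - o);
    da.cols(3 * h, 4 * h - 1) = (dc % i) % (1.0 - g % g);
    DA.rows(rows) = da;
    dh_next = da * Ut;
    dc_next = dc % f;
  }
  mat gW = xmat.t() * DA;
  mat gU = HP.t() * DA;
  rowvec gb = sum(DA, 0);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("W") = gW, Rcpp::Named("U") = gU,
      Rcpp::Named("b") = Rcpp::NumericVector(gb.begin(), gb.end()));
  if (want_dx) {
    mat dx = DA * W.t();
    return Rcpp::List::create(Rcpp::Named("grads") = out,
                              Rcpp::Named("dx") = dx);
  }
  return Rcpp::List::create(Rcpp::Named("grads") = out);
}
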