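#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12; // denominator floor for multiplicative updates

// KL objective sum_ij [ V log(V/WH) - V + WH ], 0 log 0 = 0.
static double kl_objective(const mat& V, const mat& WH) {
  mat WHc = arma::max(WH, mat(WH.n_rows, WH.n_cols, fill::value(EPS)));
  // replace V==0 by 1 inside the log; the term is multiplied by V=0 anyway
  mat Vsafe = V;
  Vsafe.elem(find(Vsafe == 0.0)).ones();
  return accu(V % arma::log(Vsafe / WHc)) - accu(V) + accu(WH);
}

// Lee-Seung multiplicative updates for the KL objective.
// W and H are the (strictly positive) initial matrices; updated in place.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, bool track) {
  const uword N = V.n_rows, M = V.n_cols;
  if (W.n_rows != N || H.n_cols != M || W.n_cols != H.n_rows)
    Rcpp::stop("non-conformant shapes in nmf_kl_cpp");

  std::vector<double> trace;
  mat WH = W * H;
  double obj = kl_objective(V, WH);
  if (track) trace.push_back(obj);
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // H <- H .* (W' (V ./ WH)) ./ (W' 1)
    mat R1 = V / arma::max(WH, mat(N, M, fill::value(EPS)));
    rowvec wsum = sum(W, 0);
    wsum.transform([](double x) { return x < EPS ? EPS : x; });
    H = H % (W.t() * R1);
    H.each_col() /= wsum.t();

    // W <- W .* ((V ./ WH) H') ./ (1 H')
    WH = W * H;
    mat R2 = V / arma::max(WH, mat(N, M, fill::value(EPS)));
    colvec hsum = sum(H, 1);
    hsum.transform([](double x) { return x < EPS ? EPS : x; });
    W = W % (R2 * H.t());
    W.each_row() /= hsum.t();

    WH = W * H;
    double obj_new = kl_objective(V, WH);
    if (!std::isfinite(obj_new))
      Rcpp::stop("non-finite KL objective at iteration %d", it);
    if (track) trace.push_back(obj_new);
    double rel = (obj - obj_new) / (std::fabs(obj) + EPS);
    obj = obj_new;
    if (rel >= 0.0 && rel < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("kl_error") = obj,
    Rcpp::Named("n_iter") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("objective_trace") =
      track ? Rcpp::wrap(trace) : R_NilValue);
}
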