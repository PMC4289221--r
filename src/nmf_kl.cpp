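#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized KL divergence D(V || WH) = sum v*log(v/wh) - v + wh (v>0 terms).
static double kl_divergence(const mat& V, const mat& WH) {
  const double eps = 1e-16;
  double d = 0.0;
  for (uword j = 0; j < V.n_cols; ++j) {
    for (uword i = 0; i < V.n_rows; ++i) {
      const double v = V(i, j);
      const double wh = WH(i, j) + eps;
      d += (v > 0.0 ? v * std::log(v / wh) - v : 0.0) + wh;
    }
  }
  return d;
}

// Multiplicative-update NMF for the generalized KL objective.
// Stops when the relative objective decrease over a `window`-iteration
// span falls below `tol`, or at max_iter. The objective is evaluated every
// `eval_every` iterations (1 = full per-iteration trace); the convergence
// window is measured in evaluated points.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int window, int eval_every) {
  const double eps = 1e-16;
  std::vector<double> trace;
  std::vector<int> trace_iter;
  trace.reserve(max_iter / eval_every + 1);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // H update
    mat R = V / (W * H + eps);
    H %= (W.t() * R);
    H.each_col() /= (sum(W, 0).t() + eps);
    // W update (R recomputed so each half-step is monotone)
    R = V / (W * H + eps);
    W %= (R * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);

    if (iter % eval_every == 0 || iter == max_iter) {
      trace.push_back(kl_divergence(V, W * H));
      trace_iter.push_back(iter);
      const int m = (int)trace.size();
      if (m > window) {
        const double prev = trace[m - 1 - window];
        const double cur = trace[m - 1];
        const double rel = (prev - cur) / std::max(std::abs(prev), eps);
        if (rel < tol) { converged = true; break; }
      }
    }
  }

  // scale W columns to unit sum, compensating in H
  rowvec cs = sum(W, 0);
  cs.transform([eps](double x) { return x > eps ? x : 1.0; });
  W.each_row() /= cs;
  H.each_col() %= cs.t();

  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("H") = H,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("trace_iterations") = trace_iter,
      Rcpp::Named("iterations") = (trace_iter.empty() ? 0 : trace_iter.back()),
      Rcpp::Named("converged") = converged);
}
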