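#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Assembles the least-squares estimating equations of the semiparametric
// additive hazards model h(t) = rho(t)'V + theta'W, where V carries the
// unrestricted time-varying coefficients (first column normally the
// baseline intercept) and W the constant coefficients.  With V = 1 this is
// the Lin-Ying constant-effects model.
//
// Inputs must be sorted by time ascending; the risk set on the interval
// (t_{k-1}, t_k] is {i : time_i >= t_k} (left-continuous convention), and
// tied events share one risk set.  Returns the blocks
//   A  = int W'(I - H)W dt,     b = int W'(I - H) dN,
//   B  = sum over events of c_i c_i'  with c_i the event's column of
//        W'(I - H)  (robust variance numerator),
// where H projects onto the columns of V within the risk set, plus the
// per-distinct-time pieces needed to reconstruct the cumulative
// time-varying paths once theta is known:
//   dR_k = Q1_k - Q2_k theta,  Q1 = (V'V)^{-1} sum_{events} V,
//   Q2   = dt (V'V)^{-1} V'W   (flattened K x (q*p), column (m-1)*q + j).
// [[Rcpp::export]]
List additive_engine(const arma::vec& time, const arma::ivec& event,
                     const arma::mat& V, const arma::mat& W) {
  const int n = time.n_elem;
  const int q = V.n_cols, p = W.n_cols;
  if ((int)event.n_elem != n || (int)V.n_rows != n || (int)W.n_rows != n)
    stop("additive_engine: input lengths differ");

  std::vector<int> first;
  for (int i = 0; i < n; ++i)
    if (i == 0 || time[i] != time[i - 1]) first.push_back(i);
  const int K = first.size();

  arma::mat Gvv(q, q, arma::fill::zeros), Gvw(q, p, arma::fill::zeros),
      Gww(p, p, arma::fill::zeros);
  arma::mat A(p, p, arma::fill::zeros), Bmat(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  arma::mat Q1(K, q, arma::fill::zeros), Q2(K, q * p, arma::fill::zeros);
  arma::vec utime(K), dts(K), nrisk(K), ndead(K);

  for (int k = K - 1; k >= 0; --k) {
    const int i0 = first[k];
    const int i1 = (k == K - 1) ? n : first[k + 1];
    for (int i = i0; i < i1; ++i) {
      const arma::rowvec vi = V.row(i), wi = W.row(i);
      Gvv += vi.t() * vi;
      Gvw += vi.t() * wi;
      Gww += wi.t() * wi;
    }
    utime[k] = time[i0];
    const double dt = utime[k] - (k > 0 ? time[first[k - 1]] : 0.0);
    dts[k] = dt;
    nrisk[k] = n - i0;

    arma::mat Gvv_inv;
    bool ok = arma::inv_sympd(Gvv_inv, Gvv);
    if (!ok) ok = arma::inv(Gvv_inv, Gvv);
    if (!ok)
      stop("time-varying design singular on the risk set at time %g",
           utime[k]);
    const arma::mat P = Gvw.t() * Gvv_inv;  // p x q
    A += dt * (Gww - P * Gvw);

    arma::vec sumVev(q, arma::fill::zeros);
    int d = 0;
    for (int i = i0; i < i1; ++i) {
      if (event[i]) {
        ++d;
        const arma::vec ci = W.row(i).t() - P * V.row(i).t();
        b += ci;
        Bmat += ci * ci.t();
        sumVev += V.row(i).t();
      }
    }
    ndead[k] = d;
    Q1.row(k) = (Gvv_inv * sumVev).t();
    const arma::mat q2 = dt * (Gvv_inv * Gvw);  // q x p
    for (int m = 0; m < p; ++m)
      for (int j = 0; j < q; ++j) Q2(k, m * q + j) = q2(j, m);
  }

  return List::create(_["A"] = A, _["b"] = b, _["B"] = Bmat,
                      _["utime"] = utime, _["dt"] = dts,
                      _["nrisk"] = nrisk, _["nevent"] = ndead,
                      _["Q1"] = Q1, _["Q2"] = Q2);
}
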