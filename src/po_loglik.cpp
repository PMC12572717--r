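#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-logit (proportional-odds) likelihood machinery.
//
// Parameter vector theta = (alpha_2, ..., alpha_K, beta_1, ..., beta_p),
// with P(Y >= j | x) = plogis(alpha_j + x * beta) for j = 2..K,
// P(Y >= 1) = 1 and P(Y >= K+1) = 0. Category probability for y = k is
// F_k - F_{k+1}. Unordered intercepts make some category probability
// non-positive; a finite barrier keeps line searches safe.

static inline double plogis_stable(double x) {
  if (x >= 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static const double BARRIER = 1e10;

// [[Rcpp::export]]
double po_nll_cpp(NumericVector theta, NumericMatrix X, IntegerVector y,
                  int n_states) {
  int n = X.nrow(), p = X.ncol(), K = n_states;
  if (theta.size() != (K - 1) + p) stop("theta has wrong length");
  double nll = 0.0, viol = 0.0;
  bool bad = false;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * theta[K - 1 + j];
    int k = y[i];
    double Fk = (k == 1) ? 1.0 : plogis_stable(theta[k - 2] + eta);
    double Fk1 = (k == K) ? 0.0 : plogis_stable(theta[k - 1] + eta);
    double pr = Fk - Fk1;
    if (pr <= 0.0) {
      bad = true;
      viol += -pr;
    } else {
      nll -= std::log(std::max(pr, 1e-300));
    }
  }
  if (bad) return BARRIER * (1.0 + viol);
  return nll;
}

// [[Rcpp::export]]
NumericVector po_nll_grad_cpp(NumericVector theta, NumericMatrix X,
                              IntegerVector y, int n_states) {
  int n = X.nrow(), p = X.ncol(), K = n_states;
  NumericVector g(K - 1 + p);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * theta[K - 1 + j];
    int k = y[i];
    double Fk = (k == 1) ? 1.0 : plogis_stable(theta[k - 2] + eta);
    double Fk1 = (k == K) ? 0.0 : plogis_stable(theta[k - 1] + eta);
    double pr = Fk - Fk1;
    if (pr < 1e-12) pr = 1e-12;  // clamp near/through the barrier
    double fk = (k == 1) ? 0.0 : Fk * (1.0 - Fk);
    double fk1 = (k == K) ? 0.0 : Fk1 * (1.0 - Fk1);
    double deta = -(fk - fk1) / pr;
    if (k >= 2) g[k - 2] += -fk / pr;
    if (k < K) g[k - 1] += fk1 / pr;
    for (int j = 0; j < p; ++j) g[K - 1 + j] += deta * X(i, j);
  }
  return g;
}

// Analytic Hessian of the negative log-likelihood (observed information).
// [[Rcpp::export]]
NumericMatrix po_nll_hess_cpp(NumericVector theta, NumericMatrix X,
                              IntegerVector y, int n_states) {
  int n = X.nrow(), p = X.ncol(), K = n_states;
  int q = K - 1 + p;
  NumericMatrix H(q, q);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * theta[K - 1 + j];
    int k = y[i];
    double Fk = (k == 1) ? 1.0 : plogis_stable(theta[k - 2] + eta);
    double Fk1 = (k == K) ? 0.0 : plogis_stable(theta[k - 1] + eta);
    double pr = Fk - Fk1;
    if (pr < 1e-12) pr = 1e-12;
    double fk = (k == 1) ? 0.0 : Fk * (1.0 - Fk);
    double fk1 = (k == K) ? 0.0 : Fk1 * (1.0 - Fk1);
    double dfk = fk * (1.0 - 2.0 * Fk);    // f'(a) wrt its argument
    double dfk1 = fk1 * (1.0 - 2.0 * Fk1);
    double p2 = pr * pr;
    // second derivatives of -log(pr) wrt a = alpha_k + eta, b = alpha_{k+1} + eta
    double haa = -dfk / pr + fk * fk / p2;
    double hbb = dfk1 / pr + fk1 * fk1 / p2;
    double hab = -fk * fk1 / p2;
    // index map: a -> alpha index k-2 (if k>=2), b -> alpha index k-1 (if k<K)
    int ia = (k >= 2) ? (k - 2) : -1;
    int ib = (k < K) ? (k - 1) : -1;
    double hee = haa + hbb + 2.0 * hab;  // wrt eta twice
    if (ia >= 0) H(ia, ia) += haa;
    if (ib >= 0) H(ib, ib) += hbb;
    if (ia >= 0 && ib >= 0) {
      H(ia, ib) += hab;
      H(ib, ia) += hab;
    }
    for (int j = 0; j < p; ++j) {
      double xj = X(i, j);
      if (ia >= 0) {
        H(ia, K - 1 + j) += (haa + hab) * xj;
        H(K - 1 + j, ia) += (haa + hab) * xj;
      }
      if (ib >= 0) {
        H(ib, K - 1 + j) += (hbb + hab) * xj;
        H(K - 1 + j, ib) += (hbb + hab) * xj;
      }
      for (int l = j; l < p; ++l) {
        double v = hee * xj * X(i, l);
        H(K - 1 + j, K - 1 + l) += v;
        if (l != j) H(K - 1 + l, K - 1 + j) += v;
      }
    }
  }
  return H;
}
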