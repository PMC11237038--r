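// Entropic Gromov-Wasserstein core: projected mirror descent with a
// log-domain Sinkhorn inner solver. Kept in C++ because the inner loop runs
// up to a few thousand iterations per outer step across hundreds of sweep
// trials.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline rowvec col_lse(const mat& A) {
  rowvec m = max(A, 0);
  return m + log(sum(exp(A.each_row() - m), 0));
}

static inline vec row_lse(const mat& A) {
  vec m = max(A, 1);
  return m + log(sum(exp(A.each_col() - m), 1));
}

// One log-domain Sinkhorn solve at temperature eps, warm-started on the
// potentials f, g. Stops at marginal tolerance `tol`, at `max_iter`, or when
// the marginal error stagnates (at temperatures far below the cost scale the
// linear convergence rate degenerates; the outer loop recomputes the cost
// tensor anyway, so crawling here is wasted work). Returns iterations used,
// or -1 on numerical failure. On exit G holds the plan (rows rescaled to
// match p exactly) and err the worst column-marginal violation.
static int sinkhorn_log(const mat& M, const vec& p, const vec& q, double eps,
                        vec& f, vec& g, double tol, int max_iter, mat& G,
                        double& err) {
  const vec lp = log(p);
  const vec lq = log(q);
  const mat negMe = -(M / eps);
  int it = 0;
  err = datum::inf;
  double err_prev = datum::inf;
  bool have_G = false;
  while (it < max_iter) {
    ++it;
    mat A = negMe;
    A.each_col() += f / eps;                     // (f_i - M_ik)/eps
    g = eps * (lq - col_lse(A).t());
    mat B = negMe;
    B.each_row() += (g / eps).t();               // (g_k - M_ik)/eps
    f = eps * (lp - row_lse(B));
    if (!f.is_finite() || !g.is_finite()) return -1;
    if (it % 5 == 0 || it == max_iter) {
      B.each_col() += f / eps;
      G = exp(B);
      have_G = true;
      err = max(abs(sum(G, 0).t() - q));
      if (err < tol || err > 0.98 * err_prev) break;
      err_prev = err;
    }
  }
  if (!have_G) {                                 // max_iter < 5 corner
    mat B = negMe;
    B.each_row() += (g / eps).t();
    B.each_col() += f / eps;
    G = exp(B);
    err = max(abs(sum(G, 0).t() - q));
  }
  G.each_col() %= p / sum(G, 1);
  return it;
}

// Round a nearly feasible nonnegative plan onto the exact marginal polytope:
// cap row and column sums at their targets, then repair the deficit with a
// rank-1 nonnegative correction. The perturbation is bounded by the
// pre-rounding marginal violation.
static void round_to_marginals(mat& G, const vec& p, const vec& q) {
  vec r = sum(G, 1);
  G.each_col() %= min(ones<vec>(p.n_elem), p / r);
  rowvec c = sum(G, 0);
  G.each_row() %= min(ones<rowvec>(q.n_elem), q.t() / c);
  vec ep = p - sum(G, 1);
  rowvec eq = q.t() - sum(G, 0);
  ep.clamp(0.0, datum::inf);
  eq.clamp(0.0, datum::inf);
  double s = accu(ep);
  if (s > 0) G += (ep * eq) / s;
  G.clamp(0.0, datum::inf);
}

static double gw_plain(const mat& D, const mat& Dp, const mat& G,
                       const vec& p, const vec& q) {
  double cst = dot(p, (D % D) * p) + dot(q, (Dp % Dp) * q);
  double val = cst - 2.0 * accu(G % (D * G * Dp));
  return val > 0 ? val : 0.0;
}

// [[Rcpp::export(name = ".entropic_gw_core")]]
Rcpp::List entropic_gw_core(const arma::mat& D, const arma::mat& Dp,
                            double eps, const arma::mat& G0, int max_outer,
                            double tol, double sk_tol, int sk_max,
                            bool anneal) {
  const int n = D.n_rows, m = Dp.n_rows;
  const vec p = ones<vec>(n) / n;
  const vec q = ones<vec>(m) / m;
  mat G = G0;
  // constant part of the gradient tensor for the squared-difference loss
  const mat cC = ((D % D) * p) * ones<rowvec>(m) +
                 ones<vec>(n) * (((Dp % Dp) * q).t());
  vec f = zeros<vec>(n), g = zeros<vec>(m);
  double gwd_prev = gw_plain(D, Dp, G, p, q);
  double err = datum::inf;
  bool converged = false;
  double best_gwd = datum::inf;
  int best_it = 0;
  int it = 0;
  while (it < max_outer) {
    ++it;
    mat tens = cC - 2.0 * (D * G * Dp);
    int sk;
    if (it == 1 && anneal) {
      // cold start: anneal the temperature down to eps so the first solve
      // does not crawl when eps is far below the cost scale; the start
      // tensor (hence the anneal path) depends on the supplied init
      double e0 = 0.05 * abs(tens).max();
      std::vector<double> stages;
      for (double e = e0; e > eps * 3.0; e /= 3.0) stages.push_back(e);
      stages.push_back(eps);
      sk = 0;
      for (double e : stages) {
        sk = sinkhorn_log(tens, p, q, e, f, g, sk_tol, sk_max, G, err);
        if (sk < 0) break;
      }
    } else {
      sk = sinkhorn_log(tens, p, q, eps, f, g, sk_tol, sk_max, G, err);
    }
    if (sk < 0) {
      return Rcpp::List::create(Rcpp::Named("overflow") = true);
    }
    double gwd = gw_plain(D, Dp, G, p, q);
    if (std::abs(gwd - gwd_prev) < tol) {
      gwd_prev = gwd;
      converged = true;
      break;
    }
    gwd_prev = gwd;
    if (gwd < best_gwd - tol) {
      best_gwd = gwd;
      best_it = it;
    } else if (it - best_it >= 100) {
      break;  // oscillating without improvement: a dead local basin
    }
  }
  round_to_marginals(G, p, q);
  gwd_prev = gw_plain(D, Dp, G, p, q);
  return Rcpp::List::create(
      Rcpp::Named("overflow") = false,
      Rcpp::Named("plan") = G,
      Rcpp::Named("gwd_plain") = gwd_prev,
      Rcpp::Named("n_iterations") = it,
      Rcpp::Named("converged") = converged);
}
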