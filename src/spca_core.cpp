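// Core alternating solver for rank-one sparse PCA with sequential deflation.
// The m-dimensional soft-threshold / bisection step dominates runtime at
// neuroimaging sizes (m ~ 3e4), hence the compiled implementation; all
// surrounding logic stays in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static arma::vec soft_thresh(const arma::vec& a, double mu) {
  return arma::sign(a) % arma::max(arma::abs(a) - mu, arma::zeros(a.n_elem));
}

// L1/L2 ratio of the soft-thresholded vector in one pass (no temporaries;
// the bisection evaluates this many times per alternation).
static inline double l1l2_ratio(const arma::vec& a, double mu) {
  double l1 = 0.0, l2 = 0.0;
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    const double t = std::fabs(a[i]) - mu;
    if (t > 0.0) { l1 += t; l2 += t * t; }
  }
  return l2 > 0.0 ? l1 / std::sqrt(l2) : -1.0;
}

// Solve max a'v s.t. ||v||_2 = 1, ||v||_1 <= c.
// v = S(a, mu)/||S(a, mu)||_2 with mu = 0 when feasible, else mu by bisection
// on [0, max|a|]; ||S(a,mu)||_1/||S(a,mu)||_2 is non-increasing in mu. The
// bracket is contracted to a relative width of bis_tol (default 1e-14, i.e.
// mu resolved to near machine precision): terminating on the ratio alone can
// leave mu off by orders of magnitude where the ratio is flat in mu, which
// shows up as ~1e-8 jitter in the alternation objective.
arma::vec solve_v_arma(const arma::vec& a, double c,
                       double bis_tol, int bis_maxit) {
  const double na2 = arma::norm(a, 2);
  if (na2 <= 0.0) stop("degenerate direction: a is the zero vector");
  arma::vec v = a / na2;
  if (arma::norm(v, 1) <= c + 1e-10) return v;

  const double hi0 = arma::abs(a).max();
  double lo = 0.0, hi = hi0;
  for (int it = 0; it < bis_maxit; ++it) {
    const double mu = 0.5 * (lo + hi);
    const double ratio = l1l2_ratio(a, mu);
    if (ratio < 0.0 || ratio < c) hi = mu;    // all zero or too sparse
    else lo = mu;
    if (hi - lo <= bis_tol * hi0) break;
  }
  // hi side guarantees ||v||_1 <= c; fall back to lo when hi thresholds
  // everything away (plateau cases such as c = 1 with a unique maximum)
  arma::vec s = soft_thresh(a, hi);
  double ns2 = arma::norm(s, 2);
  if (ns2 == 0.0) {
    s = soft_thresh(a, lo);
    ns2 = arma::norm(s, 2);
    if (ns2 == 0.0)
      stop("bisection failed: thresholding removed all entries");
  }
  return s / ns2;
}

// [[Rcpp::export(name = ".solve_v_cpp")]]
arma::vec solve_v_cpp(const arma::vec& a, double c,
                      double bis_tol = 1e-12, int bis_maxit = 100) {
  return solve_v_arma(a, c, bis_tol, bis_maxit);
}

// Sequential K-component sparse PCA.
//  - initial u per component: leading left singular vector of the current
//    residual, by power iteration on the n x n Gram matrix from the fixed
//    all-ones start;
//  - alternation: v <- argmax u'Xv (L1-constrained), u <- Xv/||Xv||;
//    objective d = u'Xv = ||Xv|| is non-decreasing;
//  - deflation: X <- X - d u v', Gram update G <- G - b b' with b = Xv.
// [[Rcpp::export(name = ".spca_core_cpp")]]
List spca_core_cpp(const arma::mat& X0, int K, double c,
                   double tol = 1e-6, int max_iter = 200,
                   double power_tol = 1e-9, int power_maxit = 10000,
                   double bis_tol = 1e-12, int bis_maxit = 100,
                   bool trace = false) {
  arma::mat X = X0;
  const arma::uword n = X.n_rows, m = X.n_cols;
  if (!X.is_finite()) stop("X contains non-finite values");
  const double fro0 = arma::norm(X, "fro");
  if (fro0 == 0.0) stop("X is the zero matrix");
  if (K < 1) stop("K must be >= 1");

  arma::mat G = X * X.t();
  arma::mat U(n, K, arma::fill::zeros), V(m, K, arma::fill::zeros);
  arma::vec d(K, arma::fill::zeros);
  arma::ivec iters(K, arma::fill::zeros);
  arma::ivec conv(K, arma::fill::zeros);
  List traces(K);
  int k_done = 0;

  for (int k = 0; k < K; ++k) {
    if (arma::norm(X, "fro") < 1e-12 * (fro0 + 1.0)) break;  // rank exhausted

    // deterministic power-iteration start
    arma::vec u(n, arma::fill::ones);
    u /= arma::norm(u, 2);
    for (int p = 0; p < power_maxit; ++p) {
      arma::vec u2 = G * u;
      const double nu = arma::norm(u2, 2);
      if (nu == 0.0) break;
      u2 /= nu;
      const double delta = arma::norm(u2 - u, 2);
      u = u2;
      if (delta < power_tol) break;
    }

    arma::vec v(m, arma::fill::zeros), vprev(m, arma::fill::zeros);
    arma::vec b;
    double dk = 0.0;
    bool converged = false;
    int it = 0;
    std::vector<double> obj;
    for (it = 1; it <= max_iter; ++it) {
      arma::vec a = X.t() * u;
      if (arma::norm(a, 2) == 0.0)
        stop("degenerate direction encountered during alternation");
      v = solve_v_arma(a, c, bis_tol, bis_maxit);
      b = X * v;
      dk = arma::norm(b, 2);
      if (dk == 0.0)
        stop("degenerate direction encountered during alternation");
      u = b / dk;
      if (trace) obj.push_back(dk);
      if (it > 1 && arma::norm(v - vprev, 2) <= tol * arma::norm(vprev, 2)) {
        converged = true;
        break;
      }
      vprev = v;
    }

    U.col(k) = u;
    V.col(k) = v;
    d(k) = dk;
    iters(k) = std::min(it, max_iter);
    conv(k) = converged ? 1 : 0;
    if (trace) traces[k] = NumericVector(obj.begin(), obj.end());
    ++k_done;

    X -= b * v.t();     // d * u * v'
    G -= b * b.t();
  }

  return List::create(
    _["U"] = U.cols(0, std::max(k_done - 1, 0)),
    _["V"] = V.cols(0, std::max(k_done - 1, 0)),
    _["d"] = d.head(std::max(k_done, 1)),
    _["n_iter"] = iters.head(std::max(k_done, 1)),
    _["converged"] = conv.head(std::max(k_done, 1)),
    _["trace"] = traces,
    _["k"] = k_done);
}
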