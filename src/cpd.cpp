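// Coherent Point Drift core: EM loops for the rigid and nonrigid variants.
// X is the fixed point set (N x 3), Y the moving set (M x 3); the moving set
// parameterises a Gaussian mixture fitted to X. All distances in mm.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct EStep {
  vec Pt1;      // N: posterior mass per fixed point, sum_m P(m|n)
  vec P1;       // M: posterior mass per moving point, sum_n P(m|n)
  mat PX;       // M x 3: P %*% X
  double nll;   // negative log-likelihood of the mixture (incl. outlier term)
  double entropy; // mean per-fixed-point correspondence entropy (nats)
};

// Stabilised E-step. w is the uniform-outlier weight in [0, 1).
EStep estep(const mat& X, const mat& TY, double sigma2, double w) {
  const uword N = X.n_rows, M = TY.n_rows;
  EStep es;
  es.Pt1.zeros(N);
  es.P1.zeros(M);
  es.PX.zeros(M, 3);
  es.nll = 0.0;
  es.entropy = 0.0;
  // log of the uniform-outlier constant c = (2 pi s2)^{3/2} w/(1-w) M/N
  const double log_c = (w > 0.0)
    ? 1.5 * std::log(2.0 * datum::pi * sigma2) +
      std::log(w / (1.0 - w)) + std::log(double(M) / double(N))
    : -datum::inf;
  const double log_pref = std::log((1.0 - w) / double(M)) -
    1.5 * std::log(2.0 * datum::pi * sigma2);
  vec e(M), q(M);
  for (uword n = 0; n < N; ++n) {
    const double x0 = X(n, 0), x1 = X(n, 1), x2 = X(n, 2);
    for (uword m = 0; m < M; ++m) {
      const double d0 = x0 - TY(m, 0), d1 = x1 - TY(m, 1), d2 = x2 - TY(m, 2);
      e(m) = -(d0 * d0 + d1 * d1 + d2 * d2) / (2.0 * sigma2);
    }
    const double k = e.max();
    q = exp(e - k);
    const double s = accu(q);
    // denom = s + c e^{-k}; evaluate log(denom) by log-sum-exp so that the
    // outlier term cannot overflow when sigma2 is tiny (k very negative)
    const double log_s = std::log(s);
    const double log_out = log_c - k;
    const double hi = std::max(log_s, log_out);
    const double log_denom = std::isfinite(log_out)
      ? hi + std::log1p(std::exp(std::min(log_s, log_out) - hi))
      : log_s;
    const double inv_denom = std::exp(-log_denom); // underflows safely to 0
    const vec p = q * inv_denom;
    es.Pt1(n) = s * inv_denom;
    es.P1 += p;
    es.PX += p * X.row(n);
    // log p(x_n) = log_pref + k + log(s + c e^{-k})
    es.nll -= log_pref + k + log_denom;
    // entropy of the posterior row: -sum p log p, log p = (e-k) - log_denom
    const double dotqe = dot(q, e - k);
    es.entropy += -(dotqe * inv_denom) + es.Pt1(n) * log_denom;
  }
  es.entropy /= double(N);
  return es;
}

double init_sigma2(const mat& X, const mat& Y) {
  // (1 / (3 M N)) * sum_{m,n} ||x_n - y_m||^2, via second moments
  const double N = double(X.n_rows), M = double(Y.n_rows);
  const rowvec mx = mean(X, 0), my = mean(Y, 0);
  const double sx = accu(square(X)) / N, sy = accu(square(Y)) / M;
  return (sx + sy - 2.0 * dot(mx, my)) / 3.0;
}

} // namespace

// [[Rcpp::export(name = ".rigid_cpd_core")]]
Rcpp::List rigid_cpd_core(const arma::mat& X, const arma::mat& Y, double w,
                          double tol, int max_iterations, double sigma2_floor,
                          double sigma2_init = -1.0) {
  mat R = eye(3, 3);
  vec t = zeros(3);
  // sigma2_init > 0 continues a previous run at that variance instead of the
  // broad default, preserving the basin selected by a good initialisation
  double sigma2 = (sigma2_init > 0.0) ? sigma2_init : init_sigma2(X, Y);
  if (sigma2 < sigma2_floor) sigma2 = sigma2_floor;
  std::vector<double> tr_s2, tr_obj, tr_ent;
  bool converged = false;
  int used = 0;
  double prev = datum::inf;
  mat TY = Y * R.t();
  TY.each_row() += t.t();
  const vec xsq = sum(square(X), 1);
  const vec ysq = sum(square(Y), 1);
  for (int it = 1; it <= max_iterations; ++it) {
    used = it;
    EStep es = estep(X, TY, sigma2, w);
    tr_s2.push_back(sigma2);
    tr_obj.push_back(es.nll);
    tr_ent.push_back(es.entropy);
    const double Np = accu(es.P1);
    const vec mux = (X.t() * es.Pt1) / Np;
    const vec muy = (Y.t() * es.P1) / Np;
    const mat A = es.PX.t() * Y - Np * (mux * muy.t());
    mat U, V;
    vec s;
    svd(U, s, V, A);
    vec d = ones(3);
    d(2) = (det(U * V.t()) >= 0.0) ? 1.0 : -1.0;
    R = U * diagmat(d) * V.t();
    t = mux - R * muy;
    const double xPx = dot(es.Pt1, xsq) - Np * dot(mux, mux);
    const double yPy = dot(es.P1, ysq) - Np * dot(muy, muy);
    sigma2 = (xPx + yPy - 2.0 * dot(s, d)) / (3.0 * Np);
    TY = Y * R.t();
    TY.each_row() += t.t();
    if (sigma2 <= sigma2_floor) {
      // variance collapsed to the floor: the fit is as tight as representable
      sigma2 = sigma2_floor;
      converged = true;
      break;
    }
    if (std::isfinite(prev) &&
        std::abs(prev - es.nll) < tol * (std::abs(prev) + 1e-12)) {
      converged = true;
      break;
    }
    prev = es.nll;
  }
  return Rcpp::List::create(
    Rcpp::Named("R") = R, Rcpp::Named("t") = t,
    Rcpp::Named("sigma2") = tr_s2, Rcpp::Named("objective") = tr_obj,
    Rcpp::Named("entropy") = tr_ent, Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = used);
}

// [[Rcpp::export(name = ".gauss_affinity")]]
arma::mat gauss_affinity(const arma::mat& A, const arma::mat& B, double beta) {
  // exp(-||a_i - b_j||^2 / (2 beta^2)), rows of A against rows of B
  const vec asq = sum(square(A), 1);
  const vec bsq = sum(square(B), 1);
  mat D2 = repmat(asq, 1, B.n_rows) + repmat(bsq.t(), A.n_rows, 1) -
    2.0 * A * B.t();
  D2.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return exp(-D2 / (2.0 * beta * beta));
}

// [[Rcpp::export(name = ".nonrigid_cpd_core")]]
Rcpp::List nonrigid_cpd_core(const arma::mat& X, const arma::mat& Y,
                             double beta, double lambda, double w, double tol,
                             int max_iterations, double sigma2_floor) {
  const uword M = Y.n_rows;
  const mat G = gauss_affinity(Y, Y, beta);
  mat W = zeros(M, 3);
  mat TY = Y;
  double sigma2 = init_sigma2(X, Y);
  if (sigma2 < sigma2_floor) sigma2 = sigma2_floor;
  std::vector<double> tr_s2, tr_obj, tr_ent;
  bool converged = false, solve_failed = false;
  int used = 0;
  double prev = datum::inf;
  const vec xsq = sum(square(X), 1);
  for (int it = 1; it <= max_iterations; ++it) {
    used = it;
    EStep es = estep(X, TY, sigma2, w);
    const double penalty = 0.5 * lambda * trace(W.t() * G * W);
    const double obj = es.nll + penalty;
    tr_s2.push_back(sigma2);
    tr_obj.push_back(obj);
    tr_ent.push_back(es.entropy);
    const double Np = accu(es.P1);
    // (diag(P1) G + lambda sigma2 I) W = PX - diag(P1) Y
    mat Amat = G.each_col() % es.P1;
    Amat.diag() += lambda * sigma2;
    const mat B = es.PX - (Y.each_col() % es.P1);
    mat Wnew;
    if (!solve(Wnew, Amat, B, solve_opts::no_approx)) {
      solve_failed = true;
      break;
    }
    W = Wnew;
    TY = Y + G * W;
    const double xPx = dot(es.Pt1, xsq);
    const double trPXT = accu(es.PX % TY);
    const double yPy = dot(es.P1, sum(square(TY), 1));
    sigma2 = (xPx - 2.0 * trPXT + yPy) / (3.0 * Np);
    if (sigma2 <= sigma2_floor) {
      sigma2 = sigma2_floor;
      converged = true;
      break;
    }
    if (std::isfinite(prev) &&
        std::abs(prev - obj) < tol * (std::abs(prev) + 1e-12)) {
      converged = true;
      break;
    }
    prev = obj;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("sigma2") = tr_s2,
    Rcpp::Named("objective") = tr_obj, Rcpp::Named("entropy") = tr_ent,
    Rcpp::Named("converged") = converged, Rcpp::Named("iterations") = used,
    Rcpp::Named("solve_failed") = solve_failed);
}
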