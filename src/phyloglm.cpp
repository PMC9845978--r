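// Core fitting routines for phylogenetic logistic regression with a
// Firth-type penalty.
//
// Model: y_i ~ Bernoulli(mu_i), logit(mu_i) = x_i' beta, with working
// covariance V(alpha) = D_mu^{1/2} R(alpha) D_mu^{1/2} where
// R(alpha)_ij = exp(-alpha d_ij) on the (height-normalized) patristic
// distances. beta solves the penalized quasi-score equations
//   Xt' R^{-1} r + X' (h * (1/2 - mu)) = 0,
// with Xt = D_mu^{1/2} X, r = D_mu^{-1/2}(y - mu), working information
// J = Xt' R^{-1} Xt and generalized leverages
// h_i = [Xt J^{-1} Xt' R^{-1}]_ii. The penalty is the gradient of
// (1/2) log det J; at R = I the equations are exactly Jeffreys-penalized
// (Firth) logistic regression. alpha maximizes the penalized Gaussian
// working log-likelihood, profiled over beta; alpha values where the
// coefficient solve fails to converge are excluded from the profile.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MU_EPS = 1e-10;

struct ScoreState {
  vec g;        // penalized quasi-score
  mat J, Jinv;  // working information and inverse
  double normg;
  double resid_quad;  // r' R^{-1} r
  double sum_log_w;
};

static ScoreState score_at(const vec& y, const mat& X, const mat& Rinv,
                           const vec& beta) {
  ScoreState s;
  vec eta = X * beta;
  vec mu = 1.0 / (1.0 + exp(-eta));
  mu = clamp(mu, MU_EPS, 1.0 - MU_EPS);
  vec w = mu % (1.0 - mu);
  vec sw = sqrt(w);
  mat Xt = X.each_col() % sw;
  mat A = Rinv * Xt;                 // R^{-1} Xt
  s.J = symmatu(Xt.t() * A);
  vec r = (y - mu) / sw;
  vec Rr = Rinv * r;
  if (!inv_sympd(s.Jinv, s.J)) s.Jinv = pinv(s.J);
  vec h = sum((A * s.Jinv) % Xt, 1);  // diag of Xt J^{-1} Xt' R^{-1}
  s.g = Xt.t() * Rr + X.t() * (h % (0.5 - mu));
  s.normg = norm(s.g, 2);
  s.resid_quad = dot(r, Rr);
  s.sum_log_w = accu(log(w));
  return s;
}

// Damped Newton solve of the penalized estimating equations at fixed
// R^{-1}: steps are halved until the score norm does not increase, which
// keeps the iteration stable when R is nearly singular (small alpha).
// Returns convergence flag; beta, J and the penalized working
// log-likelihood pl are outputs.
static bool firth_newton(const vec& y, const mat& X, const mat& Rinv,
                         double logdetR, vec& beta, mat& J, double& pl,
                         int maxit, double tol) {
  ScoreState s = score_at(y, X, Rinv, beta);
  bool conv = false;
  double best_normg = s.normg;
  int stalled = 0;
  for (int it = 0; it < maxit; ++it) {
    vec delta = s.Jinv * s.g;
    double m = delta.is_empty() ? 0.0 : max(abs(delta));
    if (m > 5.0) delta *= 5.0 / m;      // cap raw step length
    double step = 1.0;
    vec trial;
    ScoreState ts;
    for (int k = 0; k < 12; ++k) {
      trial = beta + step * delta;
      ts = score_at(y, X, Rinv, trial);
      if (ts.normg <= s.normg * (1.0 + 1e-9) || step < 1e-3) break;
      step *= 0.5;
    }
    beta = trial;
    s = ts;
    if (step * max(abs(delta)) < tol) { conv = true; break; }
    // bail out when the score norm has stopped improving (pathological
    // near-singular correlation): report non-convergence cheaply
    if (s.normg < best_normg * (1.0 - 1e-3)) {
      best_normg = s.normg;
      stalled = 0;
    } else if (++stalled >= 8) {
      break;
    }
  }
  J = s.J;
  double ldJ, sgn;
  log_det(ldJ, sgn, s.J);
  pl = -0.5 * s.resid_quad - 0.5 * logdetR - 0.5 * s.sum_log_w - 0.5 * ldJ;
  return conv;
}

// Working correlation: form 0 is the pure exponential exp(-alpha d)
// (stationary two-state switching process); form 1 is the arcsine
// transform (2/pi) asin(exp(-alpha d)), the binary-scale correlation a
// latent threshold (liability) process induces at balanced prevalence.
static mat corr_matrix(const mat& D, double alpha, int form) {
  mat R = exp(-alpha * D);
  if (form == 1) R = (2.0 / datum::pi) * asin(R);
  R.diag().ones();
  return R;
}

// Cholesky-based inverse and log-determinant of R(alpha), with an
// escalating diagonal ridge if the factorization fails.
static bool corr_inverse(const mat& D, double alpha, int form, mat& Rinv,
                         double& logdetR, bool& ridged) {
  mat R = corr_matrix(D, alpha, form);
  mat L;
  double ridge = 0.0;
  ridged = false;
  for (int k = 0; k < 4; ++k) {
    if (chol(L, R + ridge * eye(size(R)), "lower")) {
      logdetR = 2.0 * accu(log(L.diag()));
      mat Linv = inv(trimatl(L));
      Rinv = Linv.t() * Linv;
      return true;
    }
    ridged = true;
    ridge = (ridge == 0.0) ? 1e-10 : ridge * 100.0;
  }
  // last resort: symmetric pseudo-inverse
  Rinv = pinv(R);
  vec ev;
  eig_sym(ev, R);
  ev = clamp(ev, 1e-12, datum::inf);
  logdetR = accu(log(ev));
  return false;
}

// Ordinary Firth-logistic solution (R = I), used as the deterministic
// initialization for every profile fit.
static vec firth_init(const vec& y, const mat& X, int maxit, double tol) {
  vec beta(X.n_cols, fill::zeros);
  mat J;
  double pl;
  mat I = eye(X.n_rows, X.n_rows);
  firth_newton(y, X, I, 0.0, beta, J, pl, maxit, tol);
  return beta;
}

struct ProfilePoint {
  double log_alpha, pl;
  vec beta;
  mat J;
  bool conv;
};

static ProfilePoint eval_alpha(const vec& y, const mat& X, const mat& D,
                               double log_alpha, int form, const vec& start,
                               int maxit, double tol, bool& any_ridge) {
  ProfilePoint p;
  p.log_alpha = log_alpha;
  mat Rinv;
  double logdetR;
  bool ridged;
  corr_inverse(D, std::exp(log_alpha), form, Rinv, logdetR, ridged);
  if (ridged) any_ridge = true;
  p.beta = start;
  p.conv = firth_newton(y, X, Rinv, logdetR, p.beta, p.J, p.pl, maxit, tol);
  if (!p.conv) p.pl = -datum::inf;   // unconverged solves never win
  return p;
}

static Rcpp::List pack_fit(const vec& beta, const mat& J, double alpha,
                           double pl, bool conv, bool at_bound, bool ridged) {
  mat Jinv;
  if (!inv_sympd(Jinv, J)) Jinv = pinv(J);
  vec se = sqrt(clamp(Jinv.diag(), 0.0, datum::inf));
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("se") = se,
    Rcpp::Named("vcov") = Jinv,
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("logLik") = pl,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("alpha_at_bound") = at_bound,
    Rcpp::Named("ridged") = ridged);
}

// Full profile fit: coarse grid over log alpha, then golden-section
// refinement inside the bracketing interval.
// [[Rcpp::export]]
Rcpp::List cpp_fit_phyloglm(const arma::vec& y, const arma::mat& X,
                            const arma::mat& D, double alpha_min,
                            double alpha_max, int n_grid, int refine_iter,
                            int maxit, double tol, int corr_form) {
  const double la = std::log(alpha_min), lb = std::log(alpha_max);
  vec beta0 = firth_init(y, X, maxit, tol);
  bool any_ridge = false;

  vec lgrid = linspace(la, lb, n_grid);
  ProfilePoint best;
  best.pl = -datum::inf;
  best.conv = false;
  int best_i = -1;
  // scan from the independence end so warm starts move from the stable
  // near-independent solution towards strongly correlated ones
  vec start = beta0;
  int declining = 0;
  for (int i = n_grid - 1; i >= 0; --i) {
    ProfilePoint p = eval_alpha(y, X, D, lgrid(i), corr_form, start, maxit, tol, any_ridge);
    if (p.conv) start = p.beta;
    if (p.pl > best.pl) { best = p; best_i = i; }
    // the profile is effectively unimodal in log alpha: once it has
    // fallen far below the running best (or solves stop converging),
    // still smaller alpha cannot win -- skip the expensive singular end
    if (best_i >= 0 && (!p.conv || p.pl < best.pl - 25.0)) {
      if (++declining >= 2) break;
    } else {
      declining = 0;
    }
  }
  if (best_i < 0) {
    // nothing converged: report the independence-end solve as partial
    ProfilePoint p = eval_alpha(y, X, D, lb, corr_form, beta0, maxit, tol, any_ridge);
    return pack_fit(p.beta, p.J, std::exp(lb),
                    -datum::inf, false, true, any_ridge);
  }

  if (refine_iter > 0) {
    double lo = lgrid(std::max(0, best_i - 1));
    double hi = lgrid(std::min(n_grid - 1, best_i + 1));
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
    ProfilePoint pc = eval_alpha(y, X, D, c, corr_form, best.beta, maxit, tol, any_ridge);
    ProfilePoint pd = eval_alpha(y, X, D, d, corr_form, best.beta, maxit, tol, any_ridge);
    if (pc.pl > best.pl) best = pc;
    if (pd.pl > best.pl) best = pd;
    for (int k = 0; k < refine_iter; ++k) {
      if (pc.pl >= pd.pl) {
        hi = d; d = c; pd = pc;
        c = hi - gr * (hi - lo);
        pc = eval_alpha(y, X, D, c, corr_form, best.beta, maxit, tol, any_ridge);
        if (pc.pl > best.pl) best = pc;
      } else {
        lo = c; c = d; pc = pd;
        d = lo + gr * (hi - lo);
        pd = eval_alpha(y, X, D, d, corr_form, best.beta, maxit, tol, any_ridge);
        if (pd.pl > best.pl) best = pd;
      }
      if (hi - lo < 2e-3) break;
    }
  }

  bool at_bound = best.log_alpha <= la + 1e-3 || best.log_alpha >= lb - 1e-3;
  return pack_fit(best.beta, best.J, std::exp(best.log_alpha), best.pl,
                  best.conv, at_bound, any_ridge);
}

// Precompute R(alpha)^{-1} and log det R over a fixed alpha grid for one
// tree, shared by every fit in a bootstrap analysis of that tree.
// [[Rcpp::export]]
Rcpp::List cpp_corr_grid(const arma::mat& D, const arma::vec& alphas,
                         int corr_form) {
  int m = alphas.n_elem;
  Rcpp::List Rinvs(m);
  vec logdets(m);
  for (int i = 0; i < m; ++i) {
    mat Rinv;
    double ld;
    bool ridged;
    corr_inverse(D, alphas(i), corr_form, Rinv, ld, ridged);
    Rinvs[i] = Rinv;
    logdets(i) = ld;
  }
  return Rcpp::List::create(Rcpp::Named("Rinv") = Rinvs,
                            Rcpp::Named("logdetR") = logdets);
}

// Grid-restricted profile fit against precomputed correlation inverses.
// [[Rcpp::export]]
Rcpp::List cpp_fit_grid(const arma::vec& y, const arma::mat& X,
                        const Rcpp::List& Rinvs, const arma::vec& logdets,
                        const arma::vec& alphas, int maxit, double tol) {
  int m = alphas.n_elem;
  vec start = firth_init(y, X, maxit, tol);
  double best_pl = -datum::inf;
  double best_alpha = alphas(m - 1);
  vec best_beta = start;
  mat best_J;
  bool best_conv = false;
  int best_i = -1;
  int declining = 0;
  for (int i = m - 1; i >= 0; --i) {   // independence end first
    const mat& Rinv = Rinvs[i];
    vec beta = start;
    mat J;
    double pl;
    bool conv = firth_newton(y, X, Rinv, logdets(i), beta, J, pl, maxit, tol);
    if (conv) start = beta;
    else pl = -datum::inf;
    if (pl > best_pl) {
      best_pl = pl; best_alpha = alphas(i); best_beta = beta;
      best_J = J; best_conv = conv; best_i = i;
    }
    if (best_i >= 0 && (!conv || pl < best_pl - 25.0)) {
      if (++declining >= 2) break;
    } else {
      declining = 0;
    }
  }
  if (best_i < 0) {
    const mat& Rinv = Rinvs[m - 1];
    vec beta = firth_init(y, X, maxit, tol);
    mat J;
    double pl;
    firth_newton(y, X, Rinv, logdets(m - 1), beta, J, pl, maxit, tol);
    return pack_fit(beta, J, alphas(m - 1), -datum::inf, false, true, false);
  }
  bool at_bound = best_i == 0 || best_i == m - 1;
  return pack_fit(best_beta, best_J, best_alpha, best_pl, best_conv,
                  at_bound, false);
}
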