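// Nonparametric ML fitting of cumulative probability models:
// one intercept per distinct outcome value, linear predictor Z * gamma,
// Newton iterations with step-halving. The intercept block of the observed
// information is tridiagonal, so each Newton step costs O(K q^2) via a
// block elimination (tridiagonal factorization + small Schur complement).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double CLIP = 38.0;     // linear-predictor clip before CDF evaluation
static const double PFLOOR = 1e-300; // guards log/derivative ratios, not the loglik test

// link codes: 0 probit, 1 logit, 2 loglog (Gumbel max), 3 cloglog (Gumbel min)

static inline double link_cdf(double x, int code) {
  switch (code) {
  case 0: return 0.5 * erfc(-x * M_SQRT1_2);
  case 1: return 1.0 / (1.0 + std::exp(-x));
  case 2: return std::exp(-std::exp(-x));
  default: return -std::expm1(-std::exp(x));
  }
}

static inline double link_surv(double x, int code) { // 1 - F, tail-accurate
  switch (code) {
  case 0: return 0.5 * erfc(x * M_SQRT1_2);
  case 1: return 1.0 / (1.0 + std::exp(x));
  case 2: return -std::expm1(-std::exp(-x));
  default: return std::exp(-std::exp(x));
  }
}

static inline double link_pdf(double x, int code) {
  switch (code) {
  case 0: return M_1_SQRT_2PI * std::exp(-0.5 * x * x);
  case 1: {
    double f = 1.0 / (1.0 + std::exp(-x));
    return f * (1.0 - f);
  }
  case 2: return std::exp(-x - std::exp(-x));
  default: return std::exp(x - std::exp(x));
  }
}

static inline double link_dpdf(double x, int code) { // f'(x)
  switch (code) {
  case 0: return -x * M_1_SQRT_2PI * std::exp(-0.5 * x * x);
  case 1: {
    double f = 1.0 / (1.0 + std::exp(-x));
    return f * (1.0 - f) * (1.0 - 2.0 * f);
  }
  case 2: return std::exp(-x - std::exp(-x)) * (std::exp(-x) - 1.0);
  default: return std::exp(x - std::exp(x)) * (1.0 - std::exp(x));
  }
}

static inline double clipv(double x) {
  if (x > CLIP) return CLIP;
  if (x < -CLIP) return -CLIP;
  return x;
}

// stable cell probability F(u) - F(l) with sentinels +-Inf
static inline double cell_prob(double l, double u, int code) {
  bool linf = !std::isfinite(l) && l < 0;
  bool uinf = !std::isfinite(u) && u > 0;
  if (linf && uinf) return 1.0;
  if (linf) return link_cdf(clipv(u), code);
  if (uinf) return link_surv(clipv(l), code);
  double lc = clipv(l), uc = clipv(u);
  double p = (lc > 0.0) ? link_surv(lc, code) - link_surv(uc, code)
                        : link_cdf(uc, code) - link_cdf(lc, code);
  // positive floor: a valid cell (u > l) never reports exactly zero mass,
  // keeping the log-likelihood finite in extreme regions of parameter space
  if (p <= 0.0) p = 1e-320;
  return p;
}

// Evaluate log-likelihood; optionally gradient and information blocks.
// ranks: 1..K per observation. Z: n x q design (may have q = 0).
// alpha: K-1 interior intercepts.
struct EvalOut {
  double loglik;
  arma::vec ga;     // gradient wrt alpha (K-1)
  arma::vec gg;     // gradient wrt gamma (q)
  arma::vec Td;     // tridiagonal diag of -Hessian alpha block (K-1)
  arma::vec Te;     // off-diagonal (K-2)
  arma::mat B;      // -Hessian alpha x gamma block (K-1) x q
  arma::mat C;      // -Hessian gamma block q x q
};

static void eval_model(const arma::ivec &ranks, const arma::mat &Z,
                       const arma::vec &alpha, const arma::vec &gamma,
                       int code, bool derivs, EvalOut &out) {
  int n = ranks.n_elem;
  int K = alpha.n_elem + 1;
  int q = Z.n_cols;
  out.loglik = 0.0;
  if (derivs) {
    out.ga.zeros(K - 1);
    out.gg.zeros(q);
    out.Td.zeros(K - 1);
    out.Te.zeros(K > 2 ? K - 2 : 0);
    out.B.zeros(K - 1, q);
    out.C.zeros(q, q);
  }
  arma::vec eta(n, arma::fill::zeros);
  if (q > 0) eta = Z * gamma;

  for (int i = 0; i < n; ++i) {
    int r = ranks(i);
    double u = (r < K) ? alpha(r - 1) - eta(i) : R_PosInf;
    double l = (r > 1) ? alpha(r - 2) - eta(i) : R_NegInf;
    double p = cell_prob(l, u, code);
    if (!(p > 0.0)) { out.loglik = R_NegInf; return; }
    out.loglik += std::log(p);
    if (!derivs) continue;

    double pg = std::max(p, PFLOOR);
    double fu = std::isfinite(u) ? link_pdf(clipv(u), code) : 0.0;
    double fl = std::isfinite(l) ? link_pdf(clipv(l), code) : 0.0;
    double a = fu / pg;  // dlogp/du
    double b = fl / pg;  // -dlogp/dl
    double dfu = std::isfinite(u) ? link_dpdf(clipv(u), code) : 0.0;
    double dfl = std::isfinite(l) ? link_dpdf(clipv(l), code) : 0.0;
    double Huu = dfu / pg - a * a;
    double Hll = -dfl / pg - b * b;
    double Hul = a * b;

    // gradient
    if (r < K) out.ga(r - 1) += a;
    if (r > 1) out.ga(r - 2) -= b;
    double gcoef = a - b; // dlogp/deta = -(a - b) times ... deta/dgamma = z
    if (q > 0) out.gg -= gcoef * Z.row(i).t();

    // -Hessian accumulation (information)
    if (r < K) out.Td(r - 1) -= Huu;
    if (r > 1) out.Td(r - 2) -= Hll;
    if (r > 1 && r < K) out.Te(r - 2) -= Hul;
    double hsum = Huu + 2.0 * Hul + Hll;
    if (q > 0) {
      arma::rowvec z = Z.row(i);
      // d2logp/dalpha_k deta = (Huu + Hul) for upper, (Hll + Hul) for lower;
      // dalpha enters with +, deta via gamma with -z, so -H contributes +(...)z
      if (r < K) out.B.row(r - 1) += (Huu + Hul) * z;
      if (r > 1) out.B.row(r - 2) += (Hll + Hul) * z;
      out.C -= hsum * (z.t() * z);
    }
  }
}

// Solve M x = rhs where M = [T B; B' C] (all blocks of -Hessian),
// T symmetric tridiagonal positive definite. Returns false if singular.
static bool block_solve(const arma::vec &Td, const arma::vec &Te,
                        const arma::mat &B, const arma::mat &C,
                        const arma::vec &ra, const arma::vec &rg,
                        arma::vec &xa, arma::vec &xg) {
  int m = Td.n_elem;
  int q = C.n_cols;
  // LDL' factorization of T: d(i), sub l(i)
  arma::vec d(m), lsub(m > 1 ? m - 1 : 0);
  d(0) = Td(0);
  if (d(0) <= 0) return false;
  for (int i = 1; i < m; ++i) {
    lsub(i - 1) = Te(i - 1) / d(i - 1);
    d(i) = Td(i) - lsub(i - 1) * Te(i - 1);
    if (d(i) <= 0) return false;
  }
  auto trisolve = [&](arma::vec v) {
    for (int i = 1; i < m; ++i) v(i) -= lsub(i - 1) * v(i - 1);
    for (int i = 0; i < m; ++i) v(i) /= d(i);
    for (int i = m - 2; i >= 0; --i) v(i) -= lsub(i) * v(i + 1);
    return v;
  };
  arma::vec v = trisolve(ra);
  if (q == 0) { xa = v; xg.set_size(0); return true; }
  arma::mat W(m, q);
  for (int j = 0; j < q; ++j) W.col(j) = trisolve(B.col(j));
  arma::mat S = C - B.t() * W;
  arma::vec rhs_g = rg - B.t() * v;
  if (!arma::solve(xg, S, rhs_g, arma::solve_opts::no_approx)) return false;
  xa = v - W * xg;
  return true;
}

static inline bool strictly_increasing(const arma::vec &a) {
  for (arma::uword i = 1; i < a.n_elem; ++i)
    if (!(a(i) > a(i - 1))) return false;
  return true;
}

// [[Rcpp::export(name = ".cpm_fit_cpp")]]
List cpm_fit_cpp(IntegerVector ranks_, NumericMatrix Z_, int K, int link_code,
                 NumericVector alpha0_, NumericVector gamma0_,
                 int maxit, double tol_grad, double tol_rel) {
  arma::ivec ranks(ranks_.begin(), ranks_.size());
  arma::mat Z(Z_.begin(), Z_.nrow(), Z_.ncol());
  arma::vec alpha(alpha0_.begin(), alpha0_.size());
  arma::vec gamma(gamma0_.begin(), gamma0_.size());
  int q = Z.n_cols;

  EvalOut ev;
  eval_model(ranks, Z, alpha, gamma, link_code, true, ev);
  double ll = ev.loglik;
  std::vector<double> trace;
  trace.push_back(ll);
  bool converged = false;
  int iter = 0;
  double gnorm = R_PosInf;

  for (iter = 0; iter < maxit; ++iter) {
    gnorm = 0.0;
    if (ev.ga.n_elem) gnorm = std::max(gnorm, arma::abs(ev.ga).max());
    if (q > 0) gnorm = std::max(gnorm, arma::abs(ev.gg).max());
    if (gnorm < tol_grad && iter > 0) { converged = true; break; }

    arma::vec da, dg;
    if (!block_solve(ev.Td, ev.Te, ev.B, ev.C, ev.ga, ev.gg, da, dg)) break;

    // Newton decrement: predicted gain 0.5 * g' H^{-1} g. When it falls
    // below resolution of the log-likelihood we are at the optimum in the
    // problem's own metric even if a high-curvature gradient component has
    // not crossed the absolute tolerance.
    double decrement = 0.5 * arma::dot(ev.ga, da);
    if (q > 0) decrement += 0.5 * arma::dot(ev.gg, dg);
    if (iter > 0 && decrement < 1e-13 * (std::fabs(ll) + 1.0)) {
      converged = true;
      break;
    }

    // step-halving: require strict intercept ordering and loglik improvement
    double t = 1.0;
    bool accepted = false;
    arma::vec alpha_new, gamma_new;
    EvalOut ev_new;
    for (int h = 0; h < 40; ++h) {
      alpha_new = alpha + t * da;
      gamma_new = (q > 0) ? arma::vec(gamma + t * dg) : gamma;
      if (alpha_new.n_elem < 2 || strictly_increasing(alpha_new)) {
        eval_model(ranks, Z, alpha_new, gamma_new, link_code, true, ev_new);
        if (std::isfinite(ev_new.loglik) && ev_new.loglik >= ll - 1e-12) {
          accepted = true;
          break;
        }
      }
      t *= 0.5;
    }
    if (!accepted) break;

    double rel = std::fabs(ev_new.loglik - ll) / (std::fabs(ll) + 1.0);
    alpha = alpha_new;
    gamma = gamma_new;
    ll = ev_new.loglik;
    ev = ev_new;
    trace.push_back(ll);
    gnorm = 0.0;
    if (ev.ga.n_elem) gnorm = std::max(gnorm, arma::abs(ev.ga).max());
    if (q > 0) gnorm = std::max(gnorm, arma::abs(ev.gg).max());
    if (rel < tol_rel && gnorm < tol_grad) { converged = true; ++iter; break; }
  }

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["gamma"] = NumericVector(gamma.begin(), gamma.end()),
    _["loglik"] = ll,
    _["converged"] = converged,
    _["iterations"] = iter,
    _["gradient_norm"] = gnorm,
    _["loglik_trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export(name = ".cpm_eval_cpp")]]
List cpm_eval_cpp(IntegerVector ranks_, NumericMatrix Z_, int K, int link_code,
                  NumericVector alpha_, NumericVector gamma_, bool schur) {
  arma::ivec ranks(ranks_.begin(), ranks_.size());
  arma::mat Z(Z_.begin(), Z_.nrow(), Z_.ncol());
  arma::vec alpha(alpha_.begin(), alpha_.size());
  arma::vec gamma(gamma_.begin(), gamma_.size());
  EvalOut ev;
  eval_model(ranks, Z, alpha, gamma, link_code, true, ev);
  List out = List::create(
    _["loglik"] = ev.loglik,
    _["grad_alpha"] = NumericVector(ev.ga.begin(), ev.ga.end()),
    _["grad_gamma"] = NumericVector(ev.gg.begin(), ev.gg.end()));
  if (schur && Z.n_cols > 0 && std::isfinite(ev.loglik)) {
    // efficient information for gamma: C - B' T^{-1} B
    int m = ev.Td.n_elem;
    arma::vec d(m), lsub(m > 1 ? m - 1 : 0);
    d(0) = ev.Td(0);
    bool ok = d(0) > 0;
    for (int i = 1; ok && i < m; ++i) {
      lsub(i - 1) = ev.Te(i - 1) / d(i - 1);
      d(i) = ev.Td(i) - lsub(i - 1) * ev.Te(i - 1);
      ok = d(i) > 0;
    }
    if (ok) {
      arma::mat W = ev.B;
      for (arma::uword j = 0; j < W.n_cols; ++j) {
        arma::vec v = W.col(j);
        for (int i = 1; i < m; ++i) v(i) -= lsub(i - 1) * v(i - 1);
        for (int i = 0; i < m; ++i) v(i) /= d(i);
        for (int i = m - 2; i >= 0; --i) v(i) -= lsub(i) * v(i + 1);
        W.col(j) = v;
      }
      arma::mat S = ev.C - ev.B.t() * W;
      out["info_gamma"] = wrap(S);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cell_prob_cpp")]]
NumericVector cell_prob_cpp(NumericVector lower, NumericVector upper, int link_code) {
  int n = lower.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cell_prob(lower[i], upper[i], link_code);
  return out;
}
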