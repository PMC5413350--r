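// Negative-binomial log-linear GLM fitting by IRLS, with Cox-Reid
// adjusted profile log-likelihood for dispersion estimation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MU_MIN = 1e-10;

// NB log-likelihood (phi = dispersion; phi -> 0 gives Poisson)
static double nb_loglik(const arma::rowvec& y, const arma::rowvec& mu,
                        double phi) {
  double ll = 0.0;
  if (phi <= 0.0) {
    for (arma::uword j = 0; j < y.n_elem; ++j)
      ll += y[j] * std::log(mu[j]) - mu[j] - std::lgamma(y[j] + 1.0);
    return ll;
  }
  double a = 1.0 / phi;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    double m = mu[j];
    ll += std::lgamma(y[j] + a) - std::lgamma(a) - std::lgamma(y[j] + 1.0)
        + y[j] * std::log(phi * m / (1.0 + phi * m))
        - a * std::log1p(phi * m);
  }
  return ll;
}

static double nb_deviance(const arma::rowvec& y, const arma::rowvec& mu,
                          double phi) {
  double dev = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    double yy = y[j], m = mu[j];
    double t1 = (yy > 0.0) ? yy * std::log(yy / m) : 0.0;
    if (phi <= 0.0) {
      dev += 2.0 * (t1 - (yy - m));
    } else {
      dev += 2.0 * (t1 - (yy + 1.0 / phi) *
                    std::log((1.0 + phi * yy) / (1.0 + phi * m)));
    }
  }
  return dev;
}

// one-gene IRLS fit; returns convergence flag, fills beta/mu/iters
static bool fit_one(const arma::rowvec& y, const arma::mat& X,
                    const arma::rowvec& off, double phi, double tol,
                    int maxit, arma::vec& beta, arma::rowvec& mu,
                    int& iters) {
  const arma::uword n = y.n_elem, p = X.n_cols;
  // initialise from working response on log scale
  arma::vec z0(n);
  for (arma::uword j = 0; j < n; ++j)
    z0[j] = std::log(y[j] + 0.125) - off[j];
  beta = arma::solve(X, z0, arma::solve_opts::fast);
  arma::vec eta = X * beta;
  mu = arma::exp(eta.t() + off);
  mu = arma::clamp(mu, MU_MIN, arma::datum::inf);
  double dev = nb_deviance(y, mu, phi);
  bool conv = false;
  iters = 0;
  for (int it = 1; it <= maxit; ++it) {
    iters = it;
    arma::vec w(n), z(n);
    for (arma::uword j = 0; j < n; ++j) {
      double m = mu[j];
      w[j] = m / (1.0 + phi * m);
      z[j] = (eta[j]) + (y[j] - m) / m;   // eta excludes offset here
    }
    arma::mat Xw = X.each_col() % arma::sqrt(w);
    arma::vec zw = z % arma::sqrt(w);
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, Xw, zw, arma::solve_opts::fast);
    if (!ok || !beta_new.is_finite()) break;
    // step halving if the deviance degrades or overflows
    double step = 1.0;
    arma::vec beta_try;
    double dev_new = arma::datum::inf;
    for (int h = 0; h < 8; ++h) {
      beta_try = beta + step * (beta_new - beta);
      arma::vec eta_try = X * beta_try;
      arma::rowvec mu_try = arma::exp(eta_try.t() + off);
      mu_try = arma::clamp(mu_try, MU_MIN, arma::datum::inf);
      dev_new = nb_deviance(y, mu_try, phi);
      if (std::isfinite(dev_new) && dev_new <= dev + 1e-8) {
        beta = beta_try; eta = eta_try; mu = mu_try;
        break;
      }
      step *= 0.5;
    }
    if (!std::isfinite(dev_new)) break;
    double rel = std::fabs(dev - dev_new) / (std::fabs(dev_new) + 1.0);
    dev = dev_new;
    if (rel < tol) { conv = true; break; }
  }
  return conv;
}

// Cox-Reid adjustment: 0.5 * log det(X' W X) at the fitted mu
static double cr_adjust(const arma::mat& X, const arma::rowvec& mu,
                        double phi) {
  arma::vec w(mu.n_elem);
  for (arma::uword j = 0; j < mu.n_elem; ++j)
    w[j] = mu[j] / (1.0 + phi * mu[j]);
  arma::mat XtWX = X.t() * (X.each_col() % w);
  double val, sign;
  arma::log_det(val, sign, XtWX);
  if (sign <= 0.0) return 0.0;
  return 0.5 * val;
}

// Fit every row of Y against one design matrix.
// Y: genes x samples; X: samples x p; offset: genes x samples (natural
// log); dispersion: per-gene phi. Returns coefficients, log-likelihood,
// deviance, iteration counts and convergence flags.
// [[Rcpp::export(name = ".nbGlmFit")]]
List nb_glm_fit(const arma::mat& Y, const arma::mat& X,
                const arma::mat& offset, const arma::vec& dispersion,
                double tol = 1e-8, int maxit = 100) {
  const arma::uword G = Y.n_rows, p = X.n_cols;
  arma::mat coef(G, p, arma::fill::zeros);
  arma::vec ll(G), dev(G);
  arma::ivec iters(G);
  LogicalVector converged(G);
  for (arma::uword g = 0; g < G; ++g) {
    arma::rowvec y = Y.row(g), off = offset.row(g);
    if (arma::accu(y) == 0.0) {
      // all-zero gene: flat fit at mu -> 0, flagged converged
      arma::rowvec mu(y.n_elem, arma::fill::value(MU_MIN));
      coef.row(g).zeros();
      ll[g] = nb_loglik(y, mu, dispersion[g]);
      dev[g] = 0.0;
      iters[g] = 0;
      converged[g] = true;
      continue;
    }
    arma::vec beta(p, arma::fill::zeros);
    arma::rowvec mu;
    int it = 0;
    bool conv = fit_one(y, X, off, dispersion[g], tol, maxit, beta, mu,
                        it);
    coef.row(g) = beta.t();
    ll[g] = nb_loglik(y, mu, dispersion[g]);
    dev[g] = nb_deviance(y, mu, dispersion[g]);
    iters[g] = it;
    converged[g] = conv;
  }
  return List::create(_["coefficients"] = coef, _["loglik"] = ll,
                      _["deviance"] = dev, _["iter"] = iters,
                      _["converged"] = converged);
}

// Cox-Reid adjusted profile log-likelihood of each gene at each
// dispersion value on a grid. Returns genes x length(phiGrid).
// [[Rcpp::export(name = ".nbAplGrid")]]
arma::mat nb_apl_grid(const arma::mat& Y, const arma::mat& X,
                      const arma::mat& offset, const arma::vec& phiGrid,
                      double tol = 1e-6, int maxit = 50) {
  const arma::uword G = Y.n_rows, K = phiGrid.n_elem;
  arma::mat apl(G, K, arma::fill::zeros);
  for (arma::uword g = 0; g < G; ++g) {
    arma::rowvec y = Y.row(g), off = offset.row(g);
    if (arma::accu(y) == 0.0) continue;   // flat in phi; contributes 0
    for (arma::uword k = 0; k < K; ++k) {
      double phi = phiGrid[k];
      arma::vec beta;
      arma::rowvec mu;
      int it = 0;
      fit_one(y, X, off, phi, tol, maxit, beta, mu, it);
      apl(g, k) = nb_loglik(y, mu, phi) - cr_adjust(X, mu, phi);
    }
  }
  return apl;
}

// Mean APL across genes at a single phi (used by golden-section
// refinement of the common dispersion).
// [[Rcpp::export(name = ".nbAplAt")]]
double nb_apl_at(const arma::mat& Y, const arma::mat& X,
                 const arma::mat& offset, double phi, double tol = 1e-6,
                 int maxit = 50) {
  const arma::uword G = Y.n_rows;
  double total = 0.0;
  arma::uword used = 0;
  for (arma::uword g = 0; g < G; ++g) {
    arma::rowvec y = Y.row(g), off = offset.row(g);
    if (arma::accu(y) == 0.0) continue;
    arma::vec beta;
    arma::rowvec mu;
    int it = 0;
    fit_one(y, X, off, phi, tol, maxit, beta, mu, it);
    total += nb_loglik(y, mu, phi) - cr_adjust(X, mu, phi);
    ++used;
  }
  return used ? total / used : 0.0;
}
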