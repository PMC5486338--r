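// Gibbs sampler for structured additive quantile regression under the
// asymmetric Laplace working likelihood, via the normal-exponential scale
// mixture y_i | z_i ~ N(eta_i + xi z_i, omega2 sigma z_i),
// z_i ~ Exp(mean sigma).  All full conditionals are closed form:
//   z_i  : generalised inverse Gaussian GIG(1/2, a, b_i), sampled through
//          the inverse-Gaussian reciprocal identity;
//   beta : multivariate normal (diffuse N(0, 1/beta_prec) prior);
//   f_j  : multivariate normal with precision A_j' W A_j + K_j / tau2_j,
//          re-centred to sum to zero with the mean absorbed into the
//          intercept (column 0 of X must be the intercept);
//   tau2 : inverse gamma;  sigma: inverse gamma.
// A Gaussian likelihood (mean regression) uses the same skeleton with
// conjugate normal / inverse-gamma updates and sigma holding the variance.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y0 = nu * nu;
  double x = mu + mu * mu * y0 / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y0 + mu * mu * y0 * y0);
  if (!(x > 0.0)) x = 1e-300;
  double u = unif_rand();
  return (u <= mu / (mu + x)) ? x : mu * mu / x;
}

// draw from N(Q^{-1} b, Q^{-1}) given precision Q
static arma::vec mvn_prec(const arma::mat& Q, const arma::vec& b) {
  arma::mat R;
  bool ok = arma::chol(R, Q);
  if (!ok) {
    ok = arma::chol(R, Q + 1e-8 * arma::eye(Q.n_rows, Q.n_cols));
    if (!ok) stop("divergent precision: Cholesky factorisation failed");
  }
  arma::vec mu = arma::solve(arma::trimatu(R),
                 arma::solve(arma::trimatl(R.t()), b));
  arma::vec zz(Q.n_rows);
  for (arma::uword i = 0; i < zz.n_elem; ++i) zz(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(R), zz);
}

static double check_loss_cpp(double u, double theta) {
  return u >= 0.0 ? u * theta : u * (theta - 1.0);
}

// [[Rcpp::export]]
List gibbs_staqr(const arma::vec& y, const arma::mat& X, List block_idx,
                 List block_K, IntegerVector block_rank, double theta,
                 bool gaussian, int iters, int burnin, int thin,
                 List priors) {
  const int n = y.n_elem, p = X.n_cols;
  const int nb = block_idx.size();
  const double beta_prec = as<double>(priors["beta_prec"]);
  const double tau_a = as<double>(priors["tau_a"]);
  const double tau_b = as<double>(priors["tau_b"]);
  const double sig_a = as<double>(priors["sig_a"]);
  const double sig_b = as<double>(priors["sig_b"]);

  double xi = 0.0, om2 = 1.0;
  if (!gaussian) {
    xi = (1.0 - 2.0 * theta) / (theta * (1.0 - theta));
    om2 = 2.0 / (theta * (1.0 - theta));
  }

  std::vector<arma::uvec> idx(nb);
  std::vector<arma::mat> K(nb);
  std::vector<arma::vec> f(nb);
  arma::vec tau2(nb, arma::fill::ones);
  for (int j = 0; j < nb; ++j) {
    idx[j] = as<arma::uvec>(block_idx[j]);
    K[j] = as<arma::mat>(block_K[j]);
    f[j] = arma::zeros(K[j].n_rows);
  }

  arma::vec beta = arma::zeros(p);
  // start from the least squares fit for a sane chain origin
  {
    arma::mat XtX = X.t() * X + 1e-8 * arma::eye(p, p);
    beta = arma::solve(XtX, X.t() * y);
  }
  arma::vec Xb = X * beta;
  arma::vec fsum = arma::zeros(n);
  arma::vec z = arma::ones(n);
  double sigma = gaussian ? arma::var(y - Xb) : 1.0;

  const int ndraw = (iters - burnin) / thin;
  arma::mat beta_draws(ndraw, p);
  arma::mat tau2_draws(ndraw, nb);
  arma::vec sigma_draws(ndraw);
  arma::vec dev_draws(ndraw);
  std::vector<arma::mat> f_draws(nb);
  for (int j = 0; j < nb; ++j) f_draws[j].set_size(ndraw, K[j].n_rows);
  arma::vec etabar = arma::zeros(n);

  int stored = 0;
  for (int it = 0; it < iters; ++it) {
    arma::vec eta = Xb + fsum;
    arma::vec w(n), ystar(n);

    if (!gaussian) {
      // latent mixing scales
      const double a_gig = 1.0 / (2.0 * theta * (1.0 - theta) * sigma);
      for (int i = 0; i < n; ++i) {
        double r = y(i) - eta(i);
        double b_gig = r * r / (om2 * sigma);
        double zi;
        if (b_gig < 1e-14) {
          zi = R::rgamma(0.5, 2.0 / a_gig);
        } else {
          double v = rinvgauss1(std::sqrt(a_gig / b_gig), a_gig);
          zi = 1.0 / v;
        }
        if (!(zi > 1e-12)) zi = 1e-12;
        if (zi > 1e12) zi = 1e12;
        z(i) = zi;
        w(i) = 1.0 / (om2 * sigma * zi);
        ystar(i) = y(i) - xi * zi;
      }
    } else {
      w.fill(1.0 / sigma);
      ystar = y;
    }

    // ---- fixed effects ----
    {
      arma::vec t = ystar - fsum;
      arma::mat Xw = X.each_col() % w;
      arma::mat Q = Xw.t() * X;
      Q.diag() += beta_prec;
      arma::vec b = Xw.t() * t;
      beta = mvn_prec(Q, b);
      if (!beta.is_finite()) stop("divergent precision: non-finite beta draw");
      Xb = X * beta;
    }

    // ---- structured blocks ----
    for (int j = 0; j < nb; ++j) {
      const int m = K[j].n_rows;
      arma::vec fj_obs = f[j].elem(idx[j]);
      arma::vec t = ystar - Xb - (fsum - fj_obs);
      arma::vec sw = arma::zeros(m), swr = arma::zeros(m);
      for (int i = 0; i < n; ++i) {
        sw(idx[j](i)) += w(i);
        swr(idx[j](i)) += w(i) * t(i);
      }
      arma::mat Q = K[j] / tau2(j);
      Q.diag() += sw + 1e-10;
      arma::vec fj = mvn_prec(Q, swr);
      if (!fj.is_finite()) stop("divergent precision: non-finite block draw");
      double mn = arma::mean(fj);
      fj -= mn;              // sum-to-zero constraint
      beta(0) += mn;         // absorbed into the intercept
      Xb += mn;
      f[j] = fj;
      // fj is centred and its removed mean already lives in Xb
      fsum = fsum - fj_obs + fj.elem(idx[j]);

      double qf = arma::as_scalar(fj.t() * K[j] * fj);
      double shape = tau_a + 0.5 * block_rank[j];
      double rate = tau_b + 0.5 * qf;
      tau2(j) = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    eta = Xb + fsum;

    // ---- scale ----
    if (!gaussian) {
      double rate = sig_b;
      for (int i = 0; i < n; ++i) {
        double rr = y(i) - eta(i) - xi * z(i);
        rate += rr * rr / (2.0 * om2 * z(i)) + z(i);
      }
      sigma = 1.0 / R::rgamma(sig_a + 1.5 * n, 1.0 / rate);
    } else {
      double ssr = arma::accu(arma::square(y - eta));
      sigma = 1.0 / R::rgamma(sig_a + 0.5 * n, 1.0 / (sig_b + 0.5 * ssr));
    }
    if (!std::isfinite(sigma) || sigma <= 0.0) {
      stop("divergent precision: non-finite scale draw");
    }

    // ---- store ----
    if (it >= burnin && (it - burnin) % thin == 0 && stored < ndraw) {
      beta_draws.row(stored) = beta.t();
      for (int j = 0; j < nb; ++j) f_draws[j].row(stored) = f[j].t();
      tau2_draws.row(stored) = tau2.t();
      sigma_draws(stored) = sigma;
      double dev = 0.0;
      if (!gaussian) {
        const double lc = std::log(theta * (1.0 - theta) / sigma);
        for (int i = 0; i < n; ++i) {
          dev += lc - check_loss_cpp((y(i) - eta(i)) / sigma, theta);
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double r = y(i) - eta(i);
          dev += -0.5 * std::log(2.0 * M_PI * sigma) - r * r / (2.0 * sigma);
        }
      }
      dev_draws(stored) = -2.0 * dev;
      etabar += eta;
      ++stored;
    }
  }
  if (stored > 0) etabar /= stored;

  List fd(nb);
  for (int j = 0; j < nb; ++j) fd[j] = f_draws[j];
  return List::create(_["beta"] = beta_draws, _["f"] = fd,
                      _["tau2"] = tau2_draws, _["sigma"] = sigma_draws,
                      _["deviance"] = dev_draws, _["etabar"] = etabar,
                      _["ndraw"] = stored);
}
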