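#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-chain Metropolis-within-Gibbs sampler for the spatio-temporal CAR
// Poisson model. eta excludes log(E); mu = exp(logE + eta). Uses R's RNG so
// runs are reproducible under set.seed().
//
// Update sweep: single-site adaptive RW Metropolis for each u_i (ICAR full
// conditional) then recentring, each v_i, then alpha, beta1 and each beta_j,
// then exact conjugate Gibbs draws for tau_u and tau_v. Proposal scales adapt
// toward the target acceptance rate during burn-in only.

static inline double rw_step(double scale) { return R::rnorm(0.0, scale); }

// [[Rcpp::export]]
List car_mcmc_chain(const arma::mat& O, const arma::mat& mask,
                    const arma::mat& logE, const arma::cube& X,
                    const arma::vec& tcodes, const List& nb,
                    const arma::vec& m, const arma::uvec& island,
                    int n_components,
                    double V_beta, double tau_shape, double tau_rate,
                    bool include_u, bool include_v, bool include_cov,
                    bool include_time,
                    int n_burnin, int n_iter, int thin,
                    double alpha0, double beta10, const arma::vec& beta0,
                    const arma::vec& u0, const arma::vec& v0,
                    double tau_u0, double tau_v0,
                    double target_accept, double init_scale) {
  const int n = O.n_rows, K = O.n_cols, p = include_cov ? X.n_slices : 0;
  const int n_isl = arma::accu(island);
  // components among non-island zones
  const int c_main = n_components - n_isl;

  arma::vec u = u0, v = v0, beta = beta0;
  double alpha = alpha0, beta1 = beta10, tau_u = tau_u0, tau_v = tau_v0;

  // neighbour lists as 0-based uvecs
  std::vector<arma::uvec> nbv(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nbi = nb[i];
    arma::uvec w(nbi.size());
    for (int j = 0; j < nbi.size(); ++j) w[j] = nbi[j] - 1;
    nbv[i] = w;
  }

  // linear predictor without logE
  arma::mat eta(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      double e = alpha;
      if (include_time) e += beta1 * tcodes[k];
      if (include_u) e += u[i];
      if (include_v) e += v[i];
      for (int j = 0; j < p; ++j) e += beta[j] * X(i, k, j);
      eta(i, k) = e;
    }

  // proposal scales and acceptance bookkeeping
  arma::vec s_u(n), s_v(n);
  s_u.fill(init_scale); s_v.fill(init_scale);
  double s_alpha = init_scale, s_beta1 = init_scale;
  arma::vec s_beta(p > 0 ? p : 1); s_beta.fill(init_scale);
  arma::vec acc_u(n, arma::fill::zeros), acc_v(n, arma::fill::zeros);
  double acc_alpha = 0, acc_beta1 = 0;
  arma::vec acc_beta(p > 0 ? p : 1, arma::fill::zeros);
  arma::vec tot_u(n, arma::fill::zeros), tot_v(n, arma::fill::zeros);
  double tot_alpha = 0, tot_beta1 = 0;
  arma::vec tot_beta(p > 0 ? p : 1, arma::fill::zeros);
  const int window = 100;
  int batch = 0;

  const int n_keep = n_iter / thin;
  const int n_par = 2 + p + 2 * n + 2;
  arma::mat draws(n_keep, n_par);
  arma::vec devs(n_keep);
  int stored = 0;

  for (int sweep = 0; sweep < n_burnin + n_iter; ++sweep) {
    const bool adapting = sweep < n_burnin;

    if (include_u) {
      for (int i = 0; i < n; ++i) {
        double prop = u[i] + rw_step(s_u[i]);
        double d = prop - u[i];
        double lr = 0.0;
        for (int k = 0; k < K; ++k) {
          if (mask(i, k) > 0) {
            double mu_ik = std::exp(logE(i, k) + eta(i, k));
            lr += O(i, k) * d - mu_ik * (std::exp(d) - 1.0);
          }
        }
        if (island[i]) {
          lr += -0.5 * tau_u * (prop * prop - u[i] * u[i]);
        } else {
          double ubar = 0.0;
          for (arma::uword jj = 0; jj < nbv[i].n_elem; ++jj) ubar += u[nbv[i][jj]];
          ubar /= m[i];
          lr += -0.5 * tau_u * m[i] *
            ((prop - ubar) * (prop - ubar) - (u[i] - ubar) * (u[i] - ubar));
        }
        tot_u[i] += 1;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          u[i] = prop;
          for (int k = 0; k < K; ++k) eta(i, k) += d;
          acc_u[i] += 1;
        }
      }
      // recentre: transfer the mean of u into the intercept (eta unchanged)
      double ubar_all = arma::mean(u);
      u -= ubar_all;
      alpha += ubar_all;
    }

    if (include_v) {
      for (int i = 0; i < n; ++i) {
        double prop = v[i] + rw_step(s_v[i]);
        double d = prop - v[i];
        double lr = -0.5 * tau_v * (prop * prop - v[i] * v[i]);
        for (int k = 0; k < K; ++k) {
          if (mask(i, k) > 0) {
            double mu_ik = std::exp(logE(i, k) + eta(i, k));
            lr += O(i, k) * d - mu_ik * (std::exp(d) - 1.0);
          }
        }
        tot_v[i] += 1;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          v[i] = prop;
          for (int k = 0; k < K; ++k) eta(i, k) += d;
          acc_v[i] += 1;
        }
      }
    }

    { // alpha
      double d = rw_step(s_alpha);
      double lr = -0.5 * ((alpha + d) * (alpha + d) - alpha * alpha) / V_beta;
      double sumO = 0, sumMu = 0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
          if (mask(i, k) > 0) {
            sumO += O(i, k);
            sumMu += std::exp(logE(i, k) + eta(i, k));
          }
      lr += sumO * d - sumMu * (std::exp(d) - 1.0);
      tot_alpha += 1;
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        alpha += d; eta += d; acc_alpha += 1;
      }
    }

    if (include_time) { // beta1 (time slope)
      double d = rw_step(s_beta1);
      double lr = -0.5 * ((beta1 + d) * (beta1 + d) - beta1 * beta1) / V_beta;
      for (int k = 0; k < K; ++k) {
        double fac = std::exp(d * tcodes[k]) - 1.0;
        for (int i = 0; i < n; ++i)
          if (mask(i, k) > 0) {
            lr += O(i, k) * d * tcodes[k] -
              std::exp(logE(i, k) + eta(i, k)) * fac;
          }
      }
      tot_beta1 += 1;
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        beta1 += d;
        for (int k = 0; k < K; ++k) eta.col(k) += d * tcodes[k];
        acc_beta1 += 1;
      }
    }

    if (include_cov) {
      for (int j = 0; j < p; ++j) {
        double d = rw_step(s_beta[j]);
        double lr = -0.5 * ((beta[j] + d) * (beta[j] + d) - beta[j] * beta[j]) / V_beta;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            if (mask(i, k) > 0) {
              double x = X(i, k, j);
              if (x != 0.0) {
                lr += O(i, k) * d * x -
                  std::exp(logE(i, k) + eta(i, k)) * (std::exp(d * x) - 1.0);
              }
            }
        tot_beta[j] += 1;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          beta[j] += d;
          for (int i = 0; i < n; ++i)
            for (int k = 0; k < K; ++k) eta(i, k) += d * X(i, k, j);
          acc_beta[j] += 1;
        }
      }
    }

    if (include_u) { // conjugate tau_u
      double qf = 0.0, isl_ss = 0.0;
      for (int i = 0; i < n; ++i) {
        if (island[i]) { isl_ss += u[i] * u[i]; continue; }
        for (arma::uword jj = 0; jj < nbv[i].n_elem; ++jj) {
          int jn = nbv[i][jj];
          if (jn > i) { double dd = u[i] - u[jn]; qf += dd * dd; }
        }
      }
      double shape = tau_shape + 0.5 * (n - n_isl - c_main) + 0.5 * n_isl;
      double rate = tau_rate + 0.5 * qf + 0.5 * isl_ss;
      tau_u = R::rgamma(shape, 1.0 / rate);
    }
    if (include_v) { // conjugate tau_v
      double shape = tau_shape + 0.5 * n;
      double rate = tau_rate + 0.5 * arma::dot(v, v);
      tau_v = R::rgamma(shape, 1.0 / rate);
    }

    // adapt proposal scales during burn-in, in windows
    if (adapting && (sweep + 1) % window == 0) {
      batch += 1;
      double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
      auto tune = [&](double& s, double& acc, double& tot) {
        if (tot > 0) s *= std::exp(step * (acc / tot - target_accept));
        acc = 0; tot = 0;
      };
      for (int i = 0; i < n; ++i) { tune(s_u[i], acc_u[i], tot_u[i]); tune(s_v[i], acc_v[i], tot_v[i]); }
      tune(s_alpha, acc_alpha, tot_alpha);
      tune(s_beta1, acc_beta1, tot_beta1);
      for (int j = 0; j < p; ++j) tune(s_beta[j], acc_beta[j], tot_beta[j]);
    }

    // store thinned post-burn-in draws
    if (sweep >= n_burnin && (sweep - n_burnin + 1) % thin == 0 && stored < n_keep) {
      int c = 0;
      draws(stored, c++) = alpha;
      draws(stored, c++) = beta1;
      for (int j = 0; j < p; ++j) draws(stored, c++) = beta[j];
      for (int i = 0; i < n; ++i) draws(stored, c++) = u[i];
      for (int i = 0; i < n; ++i) draws(stored, c++) = v[i];
      draws(stored, c++) = tau_u;
      draws(stored, c++) = tau_v;
      double dev = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
          if (mask(i, k) > 0) {
            double lp = logE(i, k) + eta(i, k);
            dev += O(i, k) * lp - std::exp(lp) - std::lgamma(O(i, k) + 1.0);
          }
      devs[stored] = -2.0 * dev;
      stored += 1;
    }
  }

  // post-burn-in acceptance rates (counters reset at the last adaptation)
  auto rate = [](double a, double t) { return t > 0 ? a / t : NA_REAL; };
  arma::vec ar_u(n), ar_v(n);
  for (int i = 0; i < n; ++i) { ar_u[i] = rate(acc_u[i], tot_u[i]); ar_v[i] = rate(acc_v[i], tot_v[i]); }
  arma::vec ar_beta(p > 0 ? p : 1);
  for (int j = 0; j < (p > 0 ? p : 1); ++j) ar_beta[j] = rate(acc_beta[j], tot_beta[j]);
  return List::create(
    _["draws"] = draws, _["deviance"] = devs,
    _["scales"] = List::create(_["u"] = s_u, _["v"] = s_v, _["alpha"] = s_alpha,
                               _["beta1"] = s_beta1, _["beta"] = s_beta),
    _["accept"] = List::create(_["u"] = ar_u, _["v"] = ar_v,
                               _["alpha"] = rate(acc_alpha, tot_alpha),
                               _["beta1"] = rate(acc_beta1, tot_beta1),
                               _["beta"] = ar_beta),
    _["n_stored"] = stored);
}
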