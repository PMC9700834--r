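#' Specify the spatio-temporal CAR Poisson model
#'
#' The full model is a BYM-style convolution model with a linear time trend:
#' `O_ik ~ Poisson(mu_ik)` with
#' `log(mu_ik) = log(E_ik) + alpha + u_i + v_i + beta1 * t_k + x_ik' beta`,
#' where `u` carries an intrinsic CAR prior on the queen-contiguity graph
#' (sum-to-zero constrained), `v` is exchangeable normal, the fixed effects
#' have flat `Normal(0, V_beta)` priors and the precisions `tau_u`, `tau_v`
#' carry `Gamma(a, b)` priors.
#'
#' @param adjacency A `queen_adjacency`.
#' @param n_periods Number of time periods.
#' @param t_codes Time codes `t_k`; default `1:n_periods`.
#' @param V_beta Prior variance of the fixed effects (default `1e6`).
#' @param tau_shape,tau_rate Gamma hyperparameters for both precisions
#'   (defaults 0.5 and 0.0005, the conventional disease-mapping choice).
#' @param include_u,include_v,include_covariates Model-ladder flags used for
#'   DIC comparison.
#' @param include_time Include the linear time trend `beta1 * t_k`; switch
#'   off for single-period or intercept-only fits (with one period the trend
#'   is confounded with the intercept).
#' @return A `car_model_spec` object.
#' @export
car_model_spec <- function(adjacency, n_periods, t_codes = seq_len(n_periods),
                           V_beta = 1e6, tau_shape = 0.5, tau_rate = 0.0005,
                           include_u = TRUE, include_v = TRUE,
                           include_covariates = TRUE, include_time = TRUE) {
  stopifnot(V_beta > 0, tau_shape > 0, tau_rate > 0,
            length(t_codes) == n_periods, all(diff(t_codes) > 0))
  structure(list(adjacency = adjacency, n_periods = n_periods, t_codes = t_codes,
                 V_beta = V_beta, tau_shape = tau_shape, tau_rate = tau_rate,
                 include_u = include_u, include_v = include_v,
                 include_covariates = include_covariates,
                 include_time = include_time),
            class = "car_model_spec")
}

#' Parameter state constructor
#'
#' @param n_zones Number of zones.
#' @param n_beta Number of covariate coefficients (9 for the three quartile
#'   variables).
#' @param alpha,beta1,beta,u,v,tau_u,tau_v Initial values; defaults are the
#'   null state (zeros, unit precisions).
#' @return A `car_parameters` list.
#' @export
car_parameters <- function(n_zones, n_beta = 9, alpha = 0, beta1 = 0,
                           beta = rep(0, n_beta), u = rep(0, n_zones),
                           v = rep(0, n_zones), tau_u = 1, tau_v = 1) {
  stopifnot(tau_u > 0, tau_v > 0, length(u) == n_zones, length(v) == n_zones)
  structure(list(alpha = alpha, beta1 = beta1, beta = beta, u = u, v = v,
                 tau_u = tau_u, tau_v = tau_v),
            class = "car_parameters")
}

#' Linear predictor of the log mean
#'
#' Returns the zones x periods matrix
#' `log E_ik + alpha + u_i + v_i + beta1 * t_k + x_ik' beta` (or a single
#' entry when `i`, `k` are given).
#'
#' @param p A `car_parameters`.
#' @param E An `expected_counts`.
#' @param X A `zone_covariates` or `NULL` for a covariate-free model.
#' @param spec A `car_model_spec` (provides `t_codes` and the include flags).
#' @param i,k Optional single zone index / period index.
#' @return Matrix of log means, or a scalar if `i` and `k` are given.
#' @export
linear_predictor <- function(p, E, X, spec, i = NULL, k = NULL) {
  nz <- length(E$zone_ids); np <- length(E$periods)
  eta <- log(E$E) + p$alpha
  if (spec$include_u) eta <- eta + p$u
  if (spec$include_v) eta <- eta + p$v
  if (spec$include_time) {
    eta <- eta + matrix(p$beta1 * spec$t_codes, nz, np, byrow = TRUE)
  }
  if (spec$include_covariates && !is.null(X)) {
    if (dim(X$X)[3] != length(p$beta)) stop("beta length does not match design array")
    for (j in seq_along(p$beta)) eta <- eta + p$beta[j] * X$X[, , j]
  }
  if (!is.null(i) && !is.null(k)) eta[i, k] else eta
}

#' Poisson log-likelihood of a count table
#'
#' `sum_ik [O_ik log mu_ik - mu_ik - log(O_ik!)]`; cells with `n = 0` are
#' skipped.
#'
#' @param C A `count_table`.
#' @param mu Matrix of Poisson means (zones x periods).
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(C, mu) {
  if (any(C$O < 0)) stop("negative observed counts")
  sel <- C$n > 0
  if (any(mu[sel] <= 0)) stop("non-positive mean at an observed cell")
  sum(C$O[sel] * log(mu[sel]) - mu[sel] - lgamma(C$O[sel] + 1))
}

icar_quadform <- function(u, A) {
  qf <- 0
  for (i in seq_along(u)) {
    js <- A$nb[[i]]
    js <- js[js > i]
    if (length(js)) qf <- qf + sum((u[i] - u[js])^2)
  }
  qf
}

#' Intrinsic CAR log-density kernel
#'
#' The improper pairwise-difference kernel
#' `((n - c)/2) log(tau_u) - (tau_u/2) * sum_{i<j} w_ij (u_i - u_j)^2`,
#' with `c` the number of connected components of the adjacency graph (the
#' rank deficiency of the ICAR precision).
#'
#' @param u Zone vector, sum-to-zero within `tol`.
#' @param tau_u Precision (> 0).
#' @param A A `queen_adjacency`.
#' @param tol Tolerance for the sum-to-zero check.
#' @return Unnormalized log density (scalar).
#' @export
icar_logdensity <- function(u, tau_u, A, tol = 1e-6) {
  if (!isTRUE(all.equal(A$W, t(A$W), check.attributes = FALSE))) {
    stop("adjacency matrix is not symmetric")
  }
  stopifnot(tau_u > 0)
  if (abs(sum(u)) > tol * max(1, length(u))) {
    stop("u does not satisfy the sum-to-zero constraint")
  }
  n <- length(u)
  (n - A$n_components) / 2 * log(tau_u) - tau_u / 2 * icar_quadform(u, A)
}

#' Joint log-prior of a parameter state
#'
#' Normal`(0, V_beta)` for the intercept, time slope and covariate
#' coefficients; the ICAR kernel for `u` (island zones contribute
#' `Normal(0, 1/tau_u)` instead); iid `Normal(0, 1/tau_v)` for `v`;
#' `Gamma(a, b)` for both precisions. Components switched off in the spec are
#' skipped.
#'
#' @param p A `car_parameters`.
#' @param spec A `car_model_spec`.
#' @return Scalar log density; `-Inf` for non-positive precisions.
#' @export
prior_logdensity <- function(p, spec) {
  if (p$tau_u <= 0 || p$tau_v <= 0) return(-Inf)
  sdb <- sqrt(spec$V_beta)
  lp <- stats::dnorm(p$alpha, 0, sdb, log = TRUE) +
    stats::dnorm(p$beta1, 0, sdb, log = TRUE)
  if (spec$include_covariates) {
    lp <- lp + sum(stats::dnorm(p$beta, 0, sdb, log = TRUE))
  }
  if (spec$include_u) {
    A <- spec$adjacency
    isl <- which(A$zone_ids %in% A$islands)
    main <- setdiff(seq_along(p$u), isl)
    u_main <- p$u[main] - mean(p$u[main])
    lp <- lp + icar_logdensity_sub(u_main, main, p$tau_u, A)
    if (length(isl)) {
      lp <- lp + sum(stats::dnorm(p$u[isl], 0, 1 / sqrt(p$tau_u), log = TRUE))
    }
    lp <- lp + stats::dgamma(p$tau_u, spec$tau_shape, rate = spec$tau_rate, log = TRUE)
  }
  if (spec$include_v) {
    lp <- lp + sum(stats::dnorm(p$v, 0, 1 / sqrt(p$tau_v), log = TRUE)) +
      stats::dgamma(p$tau_v, spec$tau_shape, rate = spec$tau_rate, log = TRUE)
  }
  lp
}

# ICAR kernel over the non-island zones only (indices `main` in A); the rank
# term counts the components among them.
icar_logdensity_sub <- function(u_main, main, tau_u, A) {
  n <- length(main)
  c_main <- A$n_components - length(A$islands)
  qf <- 0
  pos <- match(seq_along(A$zone_ids), main)
  for (ii in seq_len(n)) {
    i <- main[ii]
    js <- A$nb[[i]]
    js <- js[js > i]
    if (length(js)) qf <- qf + sum((u_main[ii] - u_main[pos[js]])^2)
  }
  (n - c_main) / 2 * log(tau_u) - tau_u / 2 * qf
}

#' Log posterior (likelihood plus prior)
#'
#' The target density of the MCMC sampler, up to the constant of
#' proportionality.
#'
#' @param p A `car_parameters`.
#' @param C A `count_table`.
#' @param E An `expected_counts`.
#' @param X A `zone_covariates` or `NULL`.
#' @param spec A `car_model_spec`.
#' @return Scalar log posterior.
#' @export
log_posterior <- function(p, C, E, X, spec) {
  mu <- exp(linear_predictor(p, E, X, spec))
  poisson_loglik(C, mu) + prior_logdensity(p, spec)
}

#' Relative risk from a log-scale coefficient
#'
#' Exponentiates a posterior mean (or credible bounds) of a log relative
#' risk and rounds to 2 decimals, the reporting convention for fixed-effect
#' tables.
#'
#' @param coef Numeric scalar or vector of log-RR values.
#' @param digits Decimals to round to (default 2).
#' @return Rounded relative risks.
#' @export
rr_from_coef <- function(coef, digits = 2) {
  stopifnot(all(is.finite(coef)))
  round(exp(coef), digits)
}
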