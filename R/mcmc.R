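#' Sampler configuration
#'
#' Defaults are a desk-scale run (2 chains of 5,000 burn-in plus 20,000
#' retained-phase sweeps thinned by 10). A long fidelity run (100,000 burn-in,
#' 1,000,000 sweeps, thin 10) is a matter of raising these numbers.
#'
#' @param n_chains Number of chains (>= 1); chain 1 starts at the null state,
#'   further chains at over-dispersed initial values.
#' @param n_burnin Burn-in sweeps, discarded; proposal scales adapt only here.
#' @param n_iter Post-burn-in sweeps; `n_iter / thin` draws are stored.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param target_accept Adaptation target for the random-walk acceptance rate.
#' @param init_scale Initial random-walk proposal SD.
#' @param init_sd SD of the over-dispersed initial values for chains >= 2.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_chains = 2, n_burnin = 5000, n_iter = 20000,
                           thin = 10, seed = 1, target_accept = 0.35,
                           init_scale = 0.1, init_sd = 0.5) {
  stopifnot(n_chains >= 1, n_burnin > 0, n_iter > 0, thin >= 1)
  structure(list(n_chains = n_chains, n_burnin = n_burnin, n_iter = n_iter,
                 thin = thin, seed = seed, target_accept = target_accept,
                 init_scale = init_scale, init_sd = init_sd),
            class = "sampler_config")
}

par_names_for <- function(zone_ids, coef_names, include_cov) {
  c("alpha", "beta1",
    if (include_cov) paste0("beta_", coef_names),
    paste0("u_", zone_ids), paste0("v_", zone_ids), "tau_u", "tau_v")
}

#' Fit the spatio-temporal CAR model by Metropolis-within-Gibbs MCMC
#'
#' One sweep updates each structured effect `u_i` by single-site adaptive
#' random-walk Metropolis against its Poisson-likelihood x ICAR full
#' conditional (then recentres `u` to sum to zero, transferring the mean into
#' the intercept), each unstructured effect `v_i` likewise, then the fixed
#' effects, and finally draws the precisions from their exact conjugate Gamma
#' full conditionals. Proposal scales adapt toward `target_accept` during
#' burn-in only, so the retained chain is a fixed-kernel Markov chain.
#'
#' @param spec A `car_model_spec`.
#' @param C A `count_table`.
#' @param E An `expected_counts`.
#' @param X A `zone_covariates`, or `NULL` when `spec$include_covariates` is
#'   `FALSE`.
#' @param cfg A `sampler_config`.
#' @return A `car_posterior`: per-chain thinned draw matrices (named columns)
#'   and deviance vectors, plus acceptance rates, final proposal scales and
#'   everything needed to reconstruct fitted relative risks (`t_codes`, `X`,
#'   `E`, zone and period ids, model flags, the config).
#' @export
run_mcmc <- function(spec, C, E, X = NULL, cfg = sampler_config()) {
  A <- spec$adjacency
  n <- length(A$zone_ids)
  stopifnot(identical(C$zone_ids, A$zone_ids), nrow(C$O) == n)
  if (spec$include_covariates && is.null(X)) stop("covariate model requires X")
  if (any(E$E[C$n > 0] <= 0)) stop("non-positive expected count at an observed cell")
  if (length(A$islands)) {
    message("adjacency has ", length(A$islands), " island zone(s): ",
            paste(A$islands, collapse = ", "),
            "; their u_i get an exchangeable Normal(0, 1/tau_u) prior")
  }

  p <- if (spec$include_covariates) dim(X$X)[3] else 0
  coef_names <- if (p > 0) dimnames(X$X)[[3]] else character(0)
  pn <- par_names_for(A$zone_ids, coef_names, spec$include_covariates)

  # check the initial state gives a finite posterior
  p0 <- car_parameters(n, n_beta = max(p, 1))
  lp0 <- log_posterior(p0, C, E, if (p > 0) X else NULL, spec)
  if (!is.finite(lp0)) stop("non-finite log posterior at the initial state ",
                            "(check for zero expected counts)")

  Xc <- if (p > 0) X$X else array(0, dim = c(n, length(C$periods), 1))
  mask <- (C$n > 0) * 1
  island <- as.integer(A$zone_ids %in% A$islands)

  set.seed(cfg$seed)
  chains <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    if (ch == 1) {
      init <- list(alpha = 0, beta1 = 0, beta = rep(0, max(p, 1)),
                   u = rep(0, n), v = rep(0, n), tau_u = 1, tau_v = 1)
    } else {
      init <- list(alpha = stats::rnorm(1, 0, cfg$init_sd),
                   beta1 = if (isTRUE(spec$include_time)) {
                     stats::rnorm(1, 0, cfg$init_sd / 2)
                   } else 0,
                   beta = if (spec$include_covariates) {
                     stats::rnorm(max(p, 1), 0, cfg$init_sd)
                   } else rep(0, max(p, 1)),
                   u = rep(0, n), v = stats::rnorm(n, 0, cfg$init_sd / 2),
                   tau_u = stats::rgamma(1, 2, 1), tau_v = stats::rgamma(1, 2, 1))
    }
    res <- car_mcmc_chain(C$O, mask, log(pmax(E$E, .Machine$double.xmin)),
                          Xc, spec$t_codes, A$nb, rowSums(A$W), island,
                          A$n_components, spec$V_beta, spec$tau_shape,
                          spec$tau_rate, spec$include_u, spec$include_v,
                          spec$include_covariates,
                          isTRUE(spec$include_time),
                          cfg$n_burnin, cfg$n_iter, cfg$thin,
                          init$alpha, init$beta1, init$beta, init$u, init$v,
                          init$tau_u, init$tau_v,
                          cfg$target_accept, cfg$init_scale)
    draws <- res$draws
    colnames(draws) <- pn
    chains[[ch]] <- list(draws = draws, deviance = as.numeric(res$deviance),
                         accept = res$accept, scales = res$scales)
  }
  structure(list(chains = chains, par_names = pn,
                 zone_ids = A$zone_ids, periods = C$periods,
                 t_codes = spec$t_codes, X = if (p > 0) X else NULL,
                 E = E, spec = spec, config = cfg),
            class = "car_posterior")
}

#' Pool draws across chains
#'
#' @param samples A `car_posterior`.
#' @param pars Optional character vector of parameter names to keep.
#' @return Matrix of pooled draws (all chains stacked).
#' @export
pooled_draws <- function(samples, pars = NULL) {
  d <- do.call(rbind, lapply(samples$chains, `[[`, "draws"))
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  d
}

#' Conjugate Gibbs draw for a random-effect precision
#'
#' For the structured effect the full conditional is
#' `Gamma(a + (n - c)/2, b + quadform/2)` with the ICAR pairwise quadratic
#' form; for the unstructured effect, `Gamma(a + n/2, b + sum(v^2)/2)`.
#'
#' @param x Random-effect vector.
#' @param A A `queen_adjacency` for the structured effect, or `NULL` for the
#'   unstructured (exchangeable) case.
#' @param shape,rate Gamma prior hyperparameters `a`, `b`.
#' @return List with the `draw` and the full-conditional `shape` and `rate`.
#' @export
conjugate_tau_update <- function(x, A = NULL, shape = 0.5, rate = 0.0005) {
  n <- length(x)
  if (is.null(A)) {
    post_shape <- shape + n / 2
    post_rate <- rate + sum(x^2) / 2
  } else {
    isl <- which(A$zone_ids %in% A$islands)
    post_shape <- shape + (n - A$n_components) / 2 + length(isl) / 2
    post_rate <- rate + icar_quadform(x, A) / 2 + sum(x[isl]^2) / 2
  }
  list(draw = stats::rgamma(1, post_shape, rate = post_rate),
       shape = post_shape, rate = post_rate)
}

#' Reconstruct a parameter state from one stored draw
#'
#' @param samples A `car_posterior`.
#' @param chain Chain index.
#' @param draw Draw index within the chain.
#' @return A `car_parameters`.
#' @export
draw_parameters <- function(samples, chain = 1, draw = 1) {
  d <- samples$chains[[chain]]$draws[draw, ]
  vec_from_draw(d, samples)
}

vec_from_draw <- function(d, samples) {
  n <- length(samples$zone_ids)
  p <- if (!is.null(samples$X)) dim(samples$X$X)[3] else 0
  beta <- if (p > 0) unname(d[paste0("beta_", dimnames(samples$X$X)[[3]])]) else numeric(0)
  car_parameters(n, n_beta = max(p, 1),
                 alpha = unname(d["alpha"]), beta1 = unname(d["beta1"]),
                 beta = if (p > 0) beta else rep(0, 1),
                 u = unname(d[paste0("u_", samples$zone_ids)]),
                 v = unname(d[paste0("v_", samples$zone_ids)]),
                 tau_u = unname(d["tau_u"]), tau_v = unname(d["tau_v"]))
}

#' Persist posterior draws as a long CSV plus a JSON manifest
#'
#' @param samples A `car_posterior`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(seq_along(samples$chains), function(ch) {
    d <- samples$chains[[ch]]$draws
    data.frame(chain = ch, draw = seq_len(nrow(d)),
               d, deviance = samples$chains[[ch]]$deviance,
               check.names = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "samples.csv"), row.names = FALSE)
  manifest <- list(
    config = unclass(samples$config),
    model = list(include_u = samples$spec$include_u,
                 include_v = samples$spec$include_v,
                 include_covariates = samples$spec$include_covariates,
                 V_beta = samples$spec$V_beta,
                 tau_shape = samples$spec$tau_shape,
                 tau_rate = samples$spec$tau_rate,
                 t_codes = samples$t_codes),
    acceptance = lapply(samples$chains, function(ch) {
      list(alpha = ch$accept$alpha, beta1 = ch$accept$beta1,
           u_mean = mean(unlist(ch$accept$u)), v_mean = mean(unlist(ch$accept$v)))
    }))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
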