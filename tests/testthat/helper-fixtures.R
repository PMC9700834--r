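# Shared fixtures, built in code. Heavier objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small simulated dataset and fitted model shared across test files.
small_sim <- function() cached("small_sim", simulate_dataset(sim_params(rows = 4, cols = 5, seed = 42)))

small_fit <- function() cached("small_fit", {
  sim <- small_sim()
  C <- sim$counts
  E <- expected_counts(C)
  spec <- car_model_spec(sim$adjacency, n_periods = 3)
  cfg <- sampler_config(n_chains = 2, n_burnin = 1000, n_iter = 4000, thin = 4, seed = 7)
  run_mcmc(spec, C, E, sim$covariates, cfg)
})

# Hand-build a car_posterior from a draws matrix, for surface tests where the
# posterior is known in closed form.
manual_posterior <- function(draws, zone_ids, periods, E,
                             t_codes = seq_along(periods), X = NULL,
                             include_time = TRUE) {
  structure(list(
    chains = list(list(draws = draws, deviance = rep(NA_real_, nrow(draws)))),
    par_names = colnames(draws), zone_ids = zone_ids, periods = periods,
    t_codes = t_codes, X = X, E = E,
    spec = list(include_u = TRUE, include_v = TRUE,
                include_covariates = !is.null(X), include_time = include_time),
    config = NULL), class = "car_posterior")
}

# Draws matrix where only alpha varies; u, v, beta1 fixed at zero.
alpha_only_draws <- function(alpha, zone_ids) {
  nd <- length(alpha)
  n <- length(zone_ids)
  d <- cbind(alpha, 0,
             matrix(0, nd, n), matrix(0, nd, n), 1, 1)
  colnames(d) <- c("alpha", "beta1", paste0("u_", zone_ids),
                   paste0("v_", zone_ids), "tau_u", "tau_v")
  d
}

# Brute-force queen contiguity on polygon vertex sets: two zones touch when
# some vertex of one lies on the boundary of the other (grid cells always
# realise contact at shared vertices).
brute_force_queen <- function(zones) {
  n <- length(zones)
  W <- matrix(0L, n, n)
  verts <- lapply(zones, function(z) unique(do.call(rbind, z$rings)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- merge(as.data.frame(verts[[i]]), as.data.frame(verts[[j]]))
    if (nrow(shared) > 0) W[i, j] <- W[j, i] <- 1L
  }
  W
}

# Constrained ICAR covariance by an independent closed form: on a connected
# graph with Laplacian Q, the sum-to-zero ICAR covariance is
# (Q + J/n)^(-1) - J/n  (J the all-ones matrix).
icar_covariance_oracle <- function(A, sigma_u) {
  Q <- diag(rowSums(A$W)) - A$W
  n <- nrow(Q)
  J <- matrix(1 / n, n, n)
  sigma_u^2 * (solve(Q + J) - J)
}

expect_silent_file <- function(path) expect_true(file.exists(path), label = path)
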