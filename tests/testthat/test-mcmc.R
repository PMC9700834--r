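test_that("the sampler is deterministic given the seed and stores the right number of draws", {
  sim <- small_sim()
  C <- sim$counts; E <- expected_counts(C)
  spec <- car_model_spec(sim$adjacency, 3)
  cfg <- sampler_config(n_chains = 2, n_burnin = 200, n_iter = 600, thin = 3, seed = 99)
  f1 <- run_mcmc(spec, C, E, sim$covariates, cfg)
  f2 <- run_mcmc(spec, C, E, sim$covariates, cfg)
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_identical(f1$chains[[2]]$draws, f2$chains[[2]]$draws)
  expect_equal(nrow(f1$chains[[1]]$draws), 200)

  # every stored structured field sums to zero
  usum <- rowSums(f1$chains[[1]]$draws[, paste0("u_", sim$counts$zone_ids)])
  expect_lt(max(abs(usum)), 1e-8)
})

test_that("stored deviance equals a full recomputation from the stored parameters", {
  fit <- small_fit()
  C <- small_sim()$counts
  for (dr in c(1, 50, nrow(fit$chains[[1]]$draws))) {
    p <- draw_parameters(fit, chain = 1, draw = dr)
    mu <- exp(linear_predictor(p, fit$E, fit$X, fit$spec))
    expect_equal(fit$chains[[1]]$deviance[dr], -2 * poisson_loglik(C, mu),
                 tolerance = 1e-8)
  }
})

test_that("conjugate precision update has the posted shape and rate", {
  W <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  A <- stcarmap:::adjacency_from_matrix(W)

  set.seed(1)
  upd0 <- conjugate_tau_update(c(0, 0), A, shape = 0.5, rate = 0.0005)
  expect_equal(upd0$shape, 0.5 + (2 - 1) / 2)
  expect_equal(upd0$rate, 0.0005)

  # fixed u on the 2-node path: quadform 4 -> rate b + 2
  upd <- conjugate_tau_update(c(1, -1), A, shape = 0.5, rate = 0.0005)
  expect_equal(upd$rate, 2.0005)

  set.seed(2)
  draws <- replicate(1e5, conjugate_tau_update(c(1, -1), A)$draw)
  m_expect <- upd$shape / upd$rate
  se <- sqrt(upd$shape) / upd$rate / sqrt(1e5)
  expect_lt(abs(mean(draws) - m_expect), 3 * se)

  # larger quadratic form -> larger rate -> stochastically smaller draws
  upd_big <- conjugate_tau_update(c(3, -3), A)
  expect_equal(upd_big$shape, upd$shape)
  expect_gt(upd_big$rate, upd$rate)

  # unstructured case
  v <- c(0.5, -0.2, 0.1)
  updv <- conjugate_tau_update(v, NULL, shape = 0.5, rate = 0.0005)
  expect_equal(updv$shape, 0.5 + 1.5)
  expect_equal(updv$rate, 0.0005 + sum(v^2) / 2)
})

test_that("intercept-only posterior matches 1-D quadrature", {
  A <- suppressWarnings(queen_adjacency(make_grid_geometry(1, 1)))
  C <- count_table(data.frame(zone_id = "Z_1_1", period = 1, O = 42, n = 80))
  E <- expected_counts(C)
  spec <- car_model_spec(A, 1, include_u = FALSE, include_v = FALSE,
                         include_covariates = FALSE, include_time = FALSE)
  cfg <- sampler_config(n_chains = 2, n_burnin = 2000, n_iter = 20000,
                        thin = 4, seed = 3)
  fit <- run_mcmc(spec, C, E, NULL, cfg)
  a <- pooled_draws(fit, "alpha")[, 1]

  grid <- seq(-2, 2, length.out = 20001)
  lp <- C$O[1, 1] * grid - E$E[1, 1] * exp(grid) - grid^2 / (2 * spec$V_beta)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  qmean <- sum(grid * w)
  qsd <- sqrt(sum((grid - qmean)^2 * w))

  mcse_mean <- mc_error(a)$mc_error
  expect_lt(abs(mean(a) - qmean), 3 * mcse_mean)
  mcse_sd <- mc_error((a - mean(a))^2)$mc_error / (2 * sd(a))
  expect_lt(abs(sd(a) - qsd), 3 * mcse_sd)
})

test_that("without random effects the posterior concentrates on the Poisson GLM fit", {
  sim <- small_sim()
  C <- sim$counts; E <- expected_counts(C)
  spec <- car_model_spec(sim$adjacency, 3, include_u = FALSE, include_v = FALSE,
                         include_covariates = FALSE)
  cfg <- sampler_config(n_chains = 1, n_burnin = 2000, n_iter = 20000,
                        thin = 4, seed = 17)
  fit <- run_mcmc(spec, C, E, NULL, cfg)
  d <- pooled_draws(fit)

  df <- as.data.frame(C)
  df$E <- as.vector(E$E)
  df$t <- as.integer(factor(df$period, levels = C$periods))
  g <- glm(O ~ t, offset = log(E), family = poisson, data = df)
  se <- summary(g)$coefficients[, "Std. Error"]
  expect_lt(abs(mean(d[, "alpha"]) - coef(g)[1]), 3 * se[1])
  expect_lt(abs(mean(d[, "beta1"]) - coef(g)[2]), 3 * se[2])
})

test_that("proposal-scale adaptation moves scales in the right direction", {
  sim <- small_sim()
  C <- sim$counts; E <- expected_counts(C)
  spec <- car_model_spec(sim$adjacency, 3, include_covariates = FALSE)
  base <- sampler_config(n_chains = 1, n_burnin = 2000, n_iter = 500, thin = 5, seed = 5)

  tiny <- base; tiny$init_scale <- 1e-3   # near-certain acceptance -> scale grows
  f_tiny <- run_mcmc(spec, C, E, NULL, tiny)
  expect_gt(f_tiny$chains[[1]]$scales$alpha, 1e-3)

  huge <- base; huge$init_scale <- 25     # near-certain rejection -> scale shrinks
  f_huge <- run_mcmc(spec, C, E, NULL, huge)
  expect_lt(f_huge$chains[[1]]$scales$alpha, 25)

  # adapted acceptance lands in a usable band around the target
  f <- small_fit()
  acc <- mean(unlist(f$chains[[1]]$accept$u))
  expect_gt(acc, 0.15)
  expect_lt(acc, 0.6)
})

test_that("a zero expected count at an observed cell is rejected up front", {
  sim <- small_sim()
  C <- sim$counts
  E <- expected_counts(C)
  E$E[1, 1] <- 0
  spec <- car_model_spec(sim$adjacency, 3)
  expect_error(run_mcmc(spec, C, E, sim$covariates, sampler_config(seed = 1)),
               "expected count")
})

test_that("samples persist as a readable long table with a manifest", {
  fit <- small_fit()
  dir <- withr::local_tempdir()
  write_samples(fit, dir)
  tab <- utils::read.csv(file.path(dir, "samples.csv"), check.names = FALSE)
  expect_equal(nrow(tab), 2 * nrow(fit$chains[[1]]$draws))
  expect_true(all(c("chain", "draw", "alpha", "deviance") %in% names(tab)))
  man <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_equal(man$config$seed, fit$config$seed)
})
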