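test_that("degenerate posteriors give point surfaces with zero-width intervals", {
  ids <- c("a", "b")
  E <- structure(list(zone_ids = ids, periods = 1,
                      E = matrix(c(10, 20), 2, dimnames = list(ids, "1")),
                      rates = 0.5), class = "expected_counts")
  s <- manual_posterior(alpha_only_draws(rep(0.2, 50), ids), ids, 1, E)
  sm <- smoothed_rr(s)
  expect_equal(sm$rr_med, rep(exp(0.2), 2))
  expect_equal(sm$rr_lo, sm$rr_hi)
  expect_equal(unname(exceedance_prob(s)[, 1]), c(1, 1))
})

test_that("lognormal posterior quantiles match the closed form", {
  ids <- "a"
  E <- structure(list(zone_ids = ids, periods = 1,
                      E = matrix(5, 1, dimnames = list(ids, "1")), rates = 1),
                 class = "expected_counts")
  set.seed(14)
  N <- 40000
  s <- manual_posterior(alpha_only_draws(rnorm(N), ids), ids, 1, E)
  sm <- smoothed_rr(s)
  expect_equal(sm$rr_med, 1, tolerance = 0.03)
  expect_equal(sm$rr_lo, exp(-1.96), tolerance = 0.05)
  expect_equal(sm$rr_hi, exp(1.96), tolerance = 0.05)
  # symmetric about the log-threshold -> exceedance 0.5 within MC error
  expect_lt(abs(exceedance_prob(s)[1, 1] - 0.5), 3 * sqrt(0.25 / N))
})

test_that("exceedance probability matches the normal tail and is monotone in the threshold", {
  ids <- "a"
  E <- structure(list(zone_ids = ids, periods = 1,
                      E = matrix(1, 1, dimnames = list(ids, "1")), rates = 1),
                 class = "expected_counts")
  m <- 0.15; sdev <- 0.2; N <- 50000
  set.seed(6)
  s <- manual_posterior(alpha_only_draws(rnorm(N, m, sdev), ids), ids, 1, E)
  p_hat <- exceedance_prob(s)[1, 1]
  p_true <- pnorm(0, m, sdev, lower.tail = FALSE)   # P(log RR > 0)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / N))

  rr <- rr_draws(s)
  for (th in c(0, 0.5, 1, 1.5)) {
    expect_gte(exceedance_prob(s, threshold = th, rr = rr)[1, 1],
               exceedance_prob(s, threshold = th + 0.5, rr = rr)[1, 1])
  }
  expect_equal(exceedance_prob(s, threshold = 0, rr = rr)[1, 1], 1)
})

test_that("relative-risk map classes follow the three-band rule", {
  expect_equal(classify_rr(c(0.5, 1.0, 1.51)), c("low", "middle", "high"))
  expect_equal(classify_rr(c(0.85, 1.1)), c("middle", "middle"))
  expect_error(classify_rr(-0.1), "negative")
})

test_that("probability map bands use closed upper bounds", {
  expect_equal(classify_prob(c(0.9, 0.1, 0.25)), c("0.8-1", "0-0.25", "0-0.25"))
  expect_equal(classify_prob(c(0.5, 0.8)), c("0.25-0.5", "0.5-0.8"))
  expect_error(classify_prob(1.2), "outside")
})

test_that("fixed-effect table reports posterior RRs with significance stars", {
  ids <- c("a", "b")
  E <- structure(list(zone_ids = ids, periods = 1,
                      E = matrix(1, 2, 1, dimnames = list(ids, "1")), rates = 1),
                 class = "expected_counts")
  d <- alpha_only_draws(rep(0.149, 100), ids)
  s <- manual_posterior(d, ids, 1, E)
  fx <- fixed_effect_table(s)
  expect_equal(fx$rr[fx$parameter == "alpha"], 1.16)

  d0 <- alpha_only_draws(rep(0, 100), ids)
  fx0 <- fixed_effect_table(manual_posterior(d0, ids, 1, E))
  expect_equal(fx0$rr[fx0$parameter == "alpha"], 1)
  expect_false(fx0$significant[fx0$parameter == "alpha"])

  set.seed(23)
  dn <- alpha_only_draws(rnorm(20000, 0.2, 0.05), ids)
  fxn <- fixed_effect_table(manual_posterior(dn, ids, 1, E))
  expect_true(fxn$significant[fxn$parameter == "alpha"])
})

test_that("surface classification is stable under draw reordering", {
  fit <- small_fit()
  C <- small_sim()$counts
  s1 <- risk_surface(fit, C)
  fit2 <- fit
  set.seed(10)
  perm <- sample(nrow(fit$chains[[1]]$draws))
  fit2$chains[[1]]$draws <- fit$chains[[1]]$draws[perm, ]
  fit2$chains[[1]]$deviance <- fit$chains[[1]]$deviance[perm]
  s2 <- risk_surface(fit2, C)
  expect_equal(s2$rr_class, s1$rr_class)
  expect_equal(s2$rr_med, s1$rr_med)
})

test_that("a strongly elevated zone earns a high exceedance probability", {
  # counts generated directly from the model: RR 1 everywhere except one zone
  # at RR 2; the fitted surface should flag that zone with P(RR > 1) > 0.8
  zones <- make_grid_geometry(4, 5)
  A <- queen_adjacency(zones)
  hits <- 0; nrep <- 6
  for (r in seq_len(nrep)) {
    set.seed(400 + r)
    n <- matrix(85L, 20, 3, dimnames = list(A$zone_ids, 1:3))
    Emat <- n * 0.5
    mu <- Emat
    mu["Z_2_3", ] <- 2 * mu["Z_2_3", ]
    O <- matrix(rpois(60, mu), 20, 3, dimnames = dimnames(n))
    C <- structure(list(zone_ids = A$zone_ids, periods = 1:3,
                        O = pmin(O, n), n = n), class = "count_table")
    E <- expected_counts(C)
    spec <- car_model_spec(A, 3, include_covariates = FALSE)
    cfg <- sampler_config(n_chains = 1, n_burnin = 1500, n_iter = 5000,
                          thin = 5, seed = 800 + r)
    fit <- run_mcmc(spec, C, E, NULL, cfg)
    ep <- exceedance_prob(fit)
    hits <- hits + all(ep["Z_2_3", ] > 0.8)
  }
  expect_gte(hits, nrep - 1)
})

test_that("risk surfaces export onto the geometry as per-period GeoJSON", {
  fit <- small_fit()
  sim <- small_sim()
  surface <- risk_surface(fit, sim$counts)
  out <- file.path(withr::local_tempdir(), "surface.geojson")
  files <- export_surface_geojson(surface, sim$zones, out)
  expect_length(files, 3)
  gj <- jsonlite::fromJSON(files[1], simplifyVector = FALSE)
  expect_equal(length(gj$features), 20)
  props <- gj$features[[1]]$properties
  expect_true(all(c("rr_med", "exc_prob", "rr_class", "zone_id") %in% names(props)))
})
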