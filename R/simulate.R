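#' Rectangular grid of unit-square zones
#'
#' A stand-in lattice for a real administrative-zone map: `rows x cols`
#' unit squares labelled `Z_<row>_<col>`, whose queen-contiguity structure is
#' known analytically (`R(C-1) + C(R-1) + 2(R-1)(C-1)` undirected edges).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @return List of zone geometries (row-major order), writable with
#'   [write_geojson()].
#' @export
make_grid_geometry <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  zones <- vector("list", rows * cols)
  idx <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    ring <- rbind(c(c - 1, r - 1), c(c, r - 1), c(c, r), c(c - 1, r), c(c - 1, r - 1))
    colnames(ring) <- c("lon", "lat")
    zones[[idx]] <- new_zone(sprintf("Z_%d_%d", r, c), list(ring))
    idx <- idx + 1L
  }
  zones
}

#' Draw a zone field from the intrinsic CAR distribution
#'
#' Exact sampling on the sum-to-zero subspace by spectral decomposition of the
#' graph Laplacian `Q = D - W`: the draw is
#' `u = sigma_u * sum_j z_j e_j / sqrt(lambda_j)` over the positive
#' eigenpairs, giving covariance `sigma_u^2 * pseudoinverse(Q)`.
#'
#' @param A A `queen_adjacency` over a connected graph.
#' @param sigma_u Marginal scale of the field (0 gives the zero vector).
#' @return Zone vector summing to zero.
#' @export
sample_icar_field <- function(A, sigma_u) {
  if (A$n_components > 1) {
    stop("adjacency graph is disconnected; ICAR field sampling needs a ",
         "connected graph")
  }
  n <- length(A$zone_ids)
  if (sigma_u == 0) return(stats::setNames(rep(0, n), A$zone_ids))
  Q <- diag(rowSums(A$W)) - A$W
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-10 * max(eg$values)
  z <- stats::rnorm(sum(pos))
  u <- eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos])) * sigma_u
  u <- as.numeric(u)
  u <- u - mean(u)   # numerically exact sum-to-zero
  stats::setNames(u, A$zone_ids)
}

#' Simulation parameters for the synthetic survey generator
#'
#' Defaults emulate the scale of a three-round national child-anemia survey
#' over a 72-zone lattice: roughly 85 children per zone-period (about 18,400
#' records), a baseline anemia rate of 0.55, a weak positive period trend and
#' quartile-covariate effects of magnitude 0.1-0.2 on the log-risk scale.
#'
#' @param rows,cols Grid dimensions (default 8 x 9 = 72 zones).
#' @param periods Period labels (default `c(2005, 2011, 2016)`).
#' @param children_per_zone Expected children per zone-period (default 85).
#' @param alpha,beta1 True intercept and per-period time slope on the log-RR
#'   scale.
#' @param beta True coefficients for the 9 quartile indicators (quartiles 2-4
#'   of low education, low SES, maternal anemia).
#' @param sigma_u,sigma_v True SDs of the structured and unstructured zone
#'   effects.
#' @param base_rate Baseline anemia proportion used for the generative
#'   expected counts.
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(rows = 8, cols = 9, periods = c(2005, 2011, 2016),
                       children_per_zone = 85,
                       alpha = -0.1, beta1 = 0.02,
                       beta = c(0.05, 0.15, 0.12, 0.06, 0.16, 0.14, 0.17, 0.2, 0.07),
                       sigma_u = 0.15, sigma_v = 0.1,
                       base_rate = 0.55, seed = 1) {
  stopifnot(rows >= 2, cols >= 2, base_rate > 0, base_rate < 1,
            children_per_zone > 0, length(beta) == 9)
  structure(list(rows = rows, cols = cols, periods = periods,
                 children_per_zone = children_per_zone, alpha = alpha,
                 beta1 = beta1, beta = beta, sigma_u = sigma_u,
                 sigma_v = sigma_v, base_rate = base_rate, seed = seed),
            class = "sim_params")
}

# Zone-level covariate proportions: a zone anchor drawn once, then a small
# per-period drift, so quartile patterns change between survey rounds as they
# do between real survey years.
sim_zone_proportions <- function(n, K, mean_p, drift_sd = 0.25) {
  anchor <- stats::rnorm(n, stats::qlogis(mean_p), 0.8)
  sapply(seq_len(K), function(k) stats::plogis(anchor + stats::rnorm(n, 0, drift_sd)))
}

#' Simulate a full synthetic survey dataset from the model
#'
#' Generates the complete input set the pipeline consumes: a grid geometry,
#' per-zone covariate proportions and their quartile design, structured
#' (ICAR) and unstructured zone effects, Poisson zone-period counts around
#' internally consistent expected counts, and individual child records whose
#' tabulation reproduces those counts. All true parameter values are returned
#' in the manifest.
#'
#' @param p A `sim_params`.
#' @return List with `zones` (geometries), `adjacency`, `records` (data
#'   frame), `counts` (`count_table`), `covariates` (`zone_covariates` built
#'   from the true zone proportions), `truth` (list of all true values and
#'   the seed).
#' @export
simulate_dataset <- function(p = sim_params()) {
  set.seed(p$seed)
  zones <- make_grid_geometry(p$rows, p$cols)
  A <- queen_adjacency(zones)
  n <- length(zones); K <- length(p$periods)
  ids <- A$zone_ids

  prop_edu <- sim_zone_proportions(n, K, 0.35)    # any education
  prop_ses <- sim_zone_proportions(n, K, 0.30)    # richer/richest
  prop_man <- sim_zone_proportions(n, K, 0.30)    # anemic mothers
  q_of <- function(pr, var) apply(pr, 2, function(col) assign_quartiles(quartile_score(col, var)))
  Xc <- zone_covariates(ids, p$periods,
                        edu_q = structure(q_of(prop_edu, "education"),
                                          dimnames = list(ids, as.character(p$periods))),
                        ses_q = structure(q_of(prop_ses, "ses"),
                                          dimnames = list(ids, as.character(p$periods))),
                        manem_q = structure(q_of(prop_man, "maternal_anemia"),
                                            dimnames = list(ids, as.character(p$periods))))

  u <- sample_icar_field(A, p$sigma_u)
  v <- stats::rnorm(n, 0, p$sigma_v)

  nmat <- matrix(stats::rpois(n * K, p$children_per_zone), n, K,
                 dimnames = list(ids, as.character(p$periods)))
  nmat[nmat == 0] <- 1L
  E <- nmat * p$base_rate
  eta_fixed <- p$alpha + matrix(p$beta1 * seq_len(K), n, K, byrow = TRUE)
  for (j in 1:9) eta_fixed <- eta_fixed + p$beta[j] * Xc$X[, , j]
  # parameter validity: the rate implied with random effects at their central
  # value must stay below 1 in every cell
  if (any(p$base_rate * exp(eta_fixed) > 1)) {
    stop("simulation parameters imply an anemia rate above 1 in expectation")
  }
  mu <- E * exp(eta_fixed + u + v)
  O <- matrix(stats::rpois(n * K, mu), n, K, dimnames = dimnames(nmat))
  capped <- O > nmat
  if (any(capped)) O[capped] <- nmat[capped]  # a child count cannot exceed n

  counts <- structure(list(zone_ids = ids, periods = p$periods,
                           O = O, n = nmat), class = "count_table")
  records <- sim_records(counts, prop_edu, prop_ses, prop_man)

  truth <- list(alpha = p$alpha, beta1 = p$beta1, beta = p$beta,
                u = u, v = v, sigma_u = p$sigma_u, sigma_v = p$sigma_v,
                base_rate = p$base_rate, E = E, mu = mu,
                n_capped = sum(capped),
                prop_edu = prop_edu, prop_ses = prop_ses, prop_man = prop_man,
                seed = p$seed)
  list(zones = zones, adjacency = A, records = records, counts = counts,
       covariates = Xc, truth = truth)
}

# Pooled anemia-severity split among anemic children (severe:moderate:mild).
severity_split <- c(severe = 736, moderate = 5400, mild = 4257)

sim_records <- function(counts, prop_edu, prop_ses, prop_man) {
  ids <- counts$zone_ids; periods <- counts$periods
  sev_p <- severity_split / sum(severity_split)
  out <- vector("list", length(ids) * length(periods))
  idx <- 1L
  for (k in seq_along(periods)) for (i in seq_along(ids)) {
    nik <- counts$n[i, k]; oik <- counts$O[i, k]
    if (nik == 0) { idx <- idx + 1L; next }
    lev <- c(sample(names(sev_p), oik, replace = TRUE, prob = sev_p),
             rep("non-anemic", nik - oik))
    edu <- ifelse(stats::runif(nik) < prop_edu[i, k],
                  sample(c("primary", "secondary", "higher"), nik, TRUE, c(0.7, 0.2, 0.1)),
                  "none")
    ses <- ifelse(stats::runif(nik) < prop_ses[i, k],
                  sample(c("richer", "richest"), nik, TRUE),
                  sample(c("poorest", "poorer", "middle"), nik, TRUE))
    man <- ifelse(stats::runif(nik) < prop_man[i, k],
                  sample(c("severe", "moderate", "mild"), nik, TRUE, c(0.05, 0.3, 0.65)),
                  "non-anemic")
    out[[idx]] <- data.frame(
      survey_year = periods[k], zone_id = ids[i], anemia_level = lev,
      maternal_education = edu, wealth_quintile = ses, maternal_anemia = man,
      maternal_age_group = sample(record_domains$maternal_age_group, nik, TRUE),
      residence = sample(record_domains$residence, nik, TRUE, c(0.15, 0.85)),
      sex = sample(record_domains$sex, nik, TRUE),
      birth_weight_class = sample(record_domains$birth_weight_class, nik, TRUE),
      birth_order_class = sample(record_domains$birth_order_class, nik, TRUE),
      stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
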