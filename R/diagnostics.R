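#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-rank-normalized) form:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` equal to `n` times the variance of the chain means.
#' Values near 1 indicate the chains have mixed.
#'
#' @param chains List of >= 2 equal-length numeric vectors.
#' @return Scalar Rhat, or `NA` with a warning when the within-chain variance
#'   is zero.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(length(chains) >= 2)
  n <- unique(lengths(chains))
  stopifnot(length(n) == 1, n >= 2)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) {
    warning("zero within-chain variance; Gelman-Rubin statistic undefined")
    return(NA_real_)
  }
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Monte Carlo standard error by batch means
#'
#' Splits the chain into `n_batches` consecutive batches; the MC error is the
#' standard deviation of the batch means divided by `sqrt(n_batches)`. The
#' conventional adequacy rule flags the parameter as converged when the MC
#' error is below 5% of the posterior SD.
#'
#' @param draws Numeric vector of posterior draws.
#' @param n_batches Number of batches (default 20).
#' @return List with `mc_error`, posterior `sd`, their `ratio` and the
#'   `pass` flag (`ratio < 0.05`).
#' @export
mc_error <- function(draws, n_batches = 20) {
  if (n_batches < 10) stop("need at least 10 batches")
  if (length(draws) < 2 * n_batches) stop("too few draws for ", n_batches, " batches")
  bsize <- floor(length(draws) / n_batches)
  use <- draws[seq_len(bsize * n_batches)]
  bm <- colMeans(matrix(use, nrow = bsize))
  mce <- stats::sd(bm) / sqrt(n_batches)
  s <- stats::sd(draws)
  ratio <- if (s > 0) mce / s else 0
  list(mc_error = mce, sd = s, ratio = ratio, pass = ratio < 0.05)
}

#' Sample autocorrelation function
#'
#' @param draws Numeric vector.
#' @param max_lag Largest lag.
#' @return Numeric vector of autocorrelations at lags `1:max_lag` (lag 0 is 1
#'   by definition and omitted).
#' @export
autocorrelation <- function(draws, max_lag = 20) {
  stopifnot(length(draws) > max_lag)
  a <- stats::acf(draws, lag.max = max_lag, plot = FALSE, demean = TRUE)
  as.numeric(a$acf)[-1]
}

#' Deviance information criterion
#'
#' `D(theta) = -2 * loglik`; `Dbar` is the posterior mean deviance, `D(thetabar)`
#' the deviance at the posterior means of the natural-scale parameters (with
#' `u` recentred), `pD = Dbar - D(thetabar)` and `DIC = Dbar + pD`
#' (Spiegelhalter's classic plug-in definition).
#'
#' @param samples A `car_posterior`.
#' @param C A `count_table`.
#' @return List with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
dic <- function(samples, C) {
  devs <- unlist(lapply(samples$chains, `[[`, "deviance"))
  if (!length(devs)) stop("no stored draws")
  bad <- which(!is.finite(devs))
  if (length(bad)) stop("non-finite deviance at stored draw ", bad[1])
  Dbar <- mean(devs)
  pm <- colMeans(pooled_draws(samples))
  pbar <- vec_from_draw(pm, samples)
  if (samples$spec$include_u) {
    shift <- mean(pbar$u)
    pbar$u <- pbar$u - shift
    pbar$alpha <- pbar$alpha + shift
  }
  mu <- exp(linear_predictor(pbar, samples$E, samples$X, samples$spec))
  Dhat <- -2 * poisson_loglik(C, mu)
  pD <- Dbar - Dhat
  list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD)
}

#' Mean-variance comparison of the outcome counts
#'
#' A Poisson outcome has variance close to its mean; a variance/mean ratio
#' well above 1 suggests overdispersion.
#'
#' @param C A `count_table`.
#' @return List with `mean`, `variance` and their `ratio` (variance/mean).
#' @export
overdispersion_check <- function(C) {
  o <- C$O[C$n > 0]
  stopifnot(length(o) > 0)
  m <- mean(o); v <- stats::var(o)
  if (is.na(v)) v <- 0
  list(mean = m, variance = v, ratio = if (m > 0) v / m else 0)
}

#' Convergence report over all scalar parameters
#'
#' @param samples A `car_posterior` with >= 2 chains (Rhat needs them).
#' @param pars Parameters to report; default the fixed effects and precisions.
#' @param max_lag Autocorrelation lags.
#' @param n_batches Batches for the MC error.
#' @return Data frame with one row per parameter: posterior mean and SD,
#'   `rhat`, `mc_error`, `mc_ratio`, `mc_pass`, `acf1`.
#' @export
diagnostics_report <- function(samples,
                               pars = grep("^(alpha|beta|tau)", samples$par_names,
                                           value = TRUE),
                               max_lag = 20, n_batches = 20) {
  rows <- lapply(pars, function(pn) {
    per_chain <- lapply(samples$chains, function(ch) ch$draws[, pn])
    pooled <- unlist(per_chain)
    rhat <- if (length(per_chain) >= 2) {
      suppressWarnings(gelman_rubin(per_chain))
    } else NA_real_
    me <- mc_error(pooled, n_batches)
    data.frame(parameter = pn, mean = mean(pooled), sd = stats::sd(pooled),
               rhat = rhat, mc_error = me$mc_error, mc_ratio = me$ratio,
               mc_pass = me$pass,
               acf1 = autocorrelation(pooled, 1)[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
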