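#' Per-draw relative-risk array
#'
#' Reconstructs `RR_ik = exp(alpha + u_i + v_i + beta1 * t_k + x_ik' beta)`
#' for every stored draw; this is the fitted risk relative to the
#' internally-standardized expectation.
#'
#' @param samples A `car_posterior`.
#' @return Array `draws x zones x periods` (chains pooled).
#' @export
rr_draws <- function(samples) {
  d <- pooled_draws(samples)
  n <- length(samples$zone_ids); K <- length(samples$periods)
  p <- if (!is.null(samples$X)) dim(samples$X$X)[3] else 0
  nd <- nrow(d)
  alpha <- d[, "alpha"]; beta1 <- d[, "beta1"]
  u <- d[, paste0("u_", samples$zone_ids), drop = FALSE]
  v <- d[, paste0("v_", samples$zone_ids), drop = FALSE]
  if (!samples$spec$include_u) u[] <- 0
  if (!samples$spec$include_v) v[] <- 0
  out <- array(NA_real_, dim = c(nd, n, K),
               dimnames = list(NULL, samples$zone_ids, as.character(samples$periods)))
  if (!isTRUE(samples$spec$include_time)) beta1 <- beta1 * 0
  for (k in seq_len(K)) {
    base <- alpha + beta1 * samples$t_codes[k]      # draws
    zone_part <- u + v                               # draws x zones
    if (p > 0) {
      xk <- samples$X$X[, k, , drop = TRUE]          # zones x p
      if (is.null(dim(xk))) xk <- matrix(xk, nrow = n)
      bet <- d[, paste0("beta_", dimnames(samples$X$X)[[3]]), drop = FALSE]
      zone_part <- zone_part + bet %*% t(xk)
    }
    out[, , k] <- exp(base + zone_part)
  }
  out
}

#' Smoothed relative risks with 95% credible intervals
#'
#' Point estimate is the posterior median of the per-draw RR (the posterior
#' mean is reported alongside); the interval is the 2.5th-97.5th posterior
#' percentile.
#'
#' @param samples A `car_posterior`.
#' @param rr Optional precomputed [rr_draws()] array.
#' @return Data frame with `zone_id`, `period`, `rr_med`, `rr_mean`, `rr_lo`,
#'   `rr_hi`.
#' @export
smoothed_rr <- function(samples, rr = rr_draws(samples)) {
  if (dim(rr)[1] == 0) stop("no stored draws")
  grid <- expand.grid(zone_id = samples$zone_ids, period = samples$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qs <- apply(rr, c(2, 3), stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  grid$rr_med <- as.vector(qs[2, , ])
  grid$rr_mean <- as.vector(apply(rr, c(2, 3), mean))
  grid$rr_lo <- as.vector(qs[1, , ])
  grid$rr_hi <- as.vector(qs[3, , ])
  grid
}

#' Posterior exceedance probability of the relative risk
#'
#' Fraction of stored draws with `RR_ik > threshold`; with the default
#' threshold 1, the posterior probability a zone-period is at elevated risk.
#'
#' @param samples A `car_posterior`.
#' @param threshold RR cutoff (default 1).
#' @param rr Optional precomputed [rr_draws()] array.
#' @return Matrix zones x periods of probabilities.
#' @export
exceedance_prob <- function(samples, threshold = 1, rr = rr_draws(samples)) {
  stopifnot(dim(rr)[1] >= 1)
  apply(rr > threshold, c(2, 3), mean)
}

#' Classify a relative risk for mapping
#'
#' Three map classes: `low` (RR < 0.85), `middle` (0.85 <= RR <= 1.1),
#' `high` (RR > 1.1).
#'
#' @param value Non-negative RR value(s).
#' @return Character vector in `c("low", "middle", "high")`.
#' @export
classify_rr <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("negative relative risk")
  out <- ifelse(value < 0.85, "low", ifelse(value <= 1.1, "middle", "high"))
  out[is.na(value)] <- NA_character_
  out
}

#' Classify an exceedance probability for mapping
#'
#' Four bands with closed upper bounds: `[0, 0.25]`, `(0.25, 0.5]`,
#' `(0.5, 0.8]`, `(0.8, 1]`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @return Character vector of band labels.
#' @export
classify_prob <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probability outside [0, 1]")
  bands <- c("0-0.25", "0.25-0.5", "0.5-0.8", "0.8-1")
  out <- bands[1 + (p > 0.25) + (p > 0.5) + (p > 0.8)]
  out[is.na(p)] <- NA_character_
  out
}

#' Fixed-effect summary table
#'
#' Posterior mean, SD and 95% credible interval of each log-scale
#' coefficient, plus the relative risk with its interval. The RR column is the
#' posterior median and percentiles of the per-draw exponentials (not
#' `exp(mean)`, though that is available via [rr_from_coef()]). A
#' significance star marks coefficients whose RR interval excludes 1.
#'
#' @param samples A `car_posterior`.
#' @param digits Decimals for the RR columns (default 2).
#' @return Data frame with one row per fixed effect (intercept, time slope,
#'   covariate coefficients).
#' @export
fixed_effect_table <- function(samples, digits = 2) {
  pars <- grep("^(alpha$|beta)", samples$par_names, value = TRUE)
  d <- pooled_draws(samples, pars)
  rows <- lapply(pars, function(pn) {
    x <- d[, pn]
    ci <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    rr <- stats::quantile(exp(x), c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(parameter = pn, mean = mean(x), sd = stats::sd(x),
               lo = ci[1], hi = ci[2],
               rr = round(rr[1], digits), rr_lo = round(rr[2], digits),
               rr_hi = round(rr[3], digits),
               significant = rr[2] > 1 | rr[3] < 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the full risk surface
#'
#' Joins the crude RR (observed/expected) with the smoothed posterior RR,
#' credible interval, exceedance probability and both map classifications.
#'
#' @param samples A `car_posterior`.
#' @param C A `count_table`.
#' @param threshold Exceedance threshold (default 1).
#' @return Data frame with columns `zone_id`, `period`, `crude_rr`, `rr_med`,
#'   `rr_mean`, `rr_lo`, `rr_hi`, `exc_prob`, `rr_class`, `prob_class`.
#' @export
risk_surface <- function(samples, C, threshold = 1) {
  rr <- rr_draws(samples)
  sm <- smoothed_rr(samples, rr)
  ep <- exceedance_prob(samples, threshold, rr)
  sm$crude_rr <- as.vector(crude_rr(C, samples$E))
  sm$exc_prob <- as.vector(ep)
  sm$rr_class <- classify_rr(sm$rr_med)
  sm$prob_class <- classify_prob(sm$exc_prob)
  sm[, c("zone_id", "period", "crude_rr", "rr_med", "rr_mean", "rr_lo",
         "rr_hi", "exc_prob", "rr_class", "prob_class")]
}

#' Export a risk surface onto zone geometries as GeoJSON
#'
#' Writes one FeatureCollection per period, joining the surface columns onto
#' each zone's properties for choropleth rendering in any GIS.
#'
#' @param surface Data frame from [risk_surface()].
#' @param zones List of zone geometries.
#' @param path Output file path; `{period}` in the name is replaced by the
#'   period label, otherwise `_<period>` is appended before the extension.
#' @return Character vector of files written, invisibly.
#' @export
export_surface_geojson <- function(surface, zones, path) {
  ids <- vapply(zones, `[[`, character(1), "zone_id")
  files <- character(0)
  for (per in unique(surface$period)) {
    sub <- surface[surface$period == per, ]
    rownames(sub) <- sub$zone_id
    features <- lapply(zones, function(z) {
      coords <- lapply(z$rings, function(r) {
        lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
      })
      props <- as.list(sub[z$zone_id, setdiff(names(sub), "zone_id")])
      props$zone_id <- z$zone_id
      list(type = "Feature", properties = props,
           geometry = list(type = "Polygon", coordinates = coords))
    })
    f <- if (grepl("\\{period\\}", path)) {
      gsub("{period}", per, path, fixed = TRUE)
    } else {
      sub("(\\.[^.]+)$", paste0("_", per, "\\1"), path)
    }
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
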