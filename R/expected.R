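#' Expected counts by internal direct standardization
#'
#' The default reference rate is the pooled rate over all zones and periods,
#' so the expected counts satisfy the internal-standardization identity
#' `sum(E) == sum(O)` and a time trend remains visible in the relative risks.
#' With `per_period = TRUE` each period is standardized to its own rate.
#' Optional stratified standardization applies pooled stratum rates to
#' per-cell stratum denominators.
#'
#' @param C A `count_table`.
#' @param per_period Standardize within each period instead of pooling.
#' @param strata Optional data frame with columns `zone_id`, `period`,
#'   `stratum`, `O`, `n` giving per-stratum cell counts; expected counts are
#'   then `sum_s n_iks * rbar_s` with `rbar_s` the pooled stratum rate.
#' @return An `expected_counts`: list with `zone_ids`, `periods`, matrix `E`
#'   and the reference `rates` used.
#' @export
expected_counts <- function(C, per_period = FALSE, strata = NULL) {
  if (sum(C$O) == 0) stop("all observed counts are zero: no reference rate")
  if (!is.null(strata)) {
    rbar <- tapply(strata$O, strata$stratum, sum) / tapply(strata$n, strata$stratum, sum)
    E <- matrix(0, length(C$zone_ids), length(C$periods),
                dimnames = dimnames(C$n))
    i <- match(strata$zone_id, C$zone_ids)
    k <- match(strata$period, C$periods)
    add <- strata$n * rbar[as.character(strata$stratum)]
    for (r in seq_len(nrow(strata))) E[i[r], k[r]] <- E[i[r], k[r]] + add[r]
    rates <- rbar
  } else if (per_period) {
    rates <- colSums(C$O) / colSums(C$n)
    E <- sweep(C$n, 2, rates, `*`)
  } else {
    rates <- sum(C$O) / sum(C$n)
    E <- C$n * rates
  }
  structure(list(zone_ids = C$zone_ids, periods = C$periods, E = E, rates = rates),
            class = "expected_counts")
}

#' Crude relative risk (standardized morbidity ratio)
#'
#' `RR_ik = O_ik / E_ik`. Cells with no children examined are reported as
#' `NA`, not 0.
#'
#' @param C A `count_table`.
#' @param E An `expected_counts`.
#' @return Matrix of crude relative risks, zones x periods.
#' @export
crude_rr <- function(C, E) {
  if (any(E$E == 0 & C$O > 0)) stop("zero expected count where observed count is positive")
  RR <- C$O / E$E
  RR[C$n == 0] <- NA_real_
  RR
}
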