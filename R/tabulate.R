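anemia_levels <- c("severe", "moderate", "mild", "non-anemic")

record_domains <- list(
  anemia_level = anemia_levels,
  maternal_education = c("none", "primary", "secondary", "higher"),
  wealth_quintile = c("poorest", "poorer", "middle", "richer", "richest"),
  maternal_anemia = anemia_levels,
  maternal_age_group = c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49"),
  residence = c("urban", "rural"),
  sex = c("male", "female"),
  birth_weight_class = c("<=2.5kg", ">2.5kg"),
  birth_order_class = c("1-3", "4-6", ">6")
)

#' Collapse a 4-level anemia status to anemic / non-anemic
#'
#' Children with mild, moderate or severe anemia (haemoglobin below the
#' age-adjusted cutoff) count as anemic.
#'
#' @param level Character vector of levels in
#'   `c("severe", "moderate", "mild", "non-anemic")`.
#' @return Character vector in `c("anemic", "non-anemic")`.
#' @export
recode_anemia <- function(level) {
  bad <- setdiff(unique(level), anemia_levels)
  if (length(bad)) stop("unknown anemia level(s): ", paste(bad, collapse = ", "))
  ifelse(level == "non-anemic", "non-anemic", "anemic")
}

#' Tabulate individual records into zone-by-period counts
#'
#' @param records Data frame of individual child records with at least
#'   `survey_year`, `zone_id` and `anemia_level` columns.
#' @param zone_ids Character vector fixing the zone order.
#' @param periods Vector of survey-year labels fixing the period order.
#' @return A `count_table`: list with `zone_ids`, `periods`, integer matrices
#'   `O` (anemic counts) and `n` (children examined), both zones x periods.
#' @export
tabulate_counts <- function(records, zone_ids, periods) {
  bad_zone <- which(!(records$zone_id %in% zone_ids))
  if (length(bad_zone)) {
    stop("record(s) ", paste(utils::head(bad_zone, 5), collapse = ", "),
         " have zone ids not in the zone order (e.g. '", records$zone_id[bad_zone[1]], "')")
  }
  bad_year <- which(!(records$survey_year %in% periods))
  if (length(bad_year)) {
    stop("record(s) ", paste(utils::head(bad_year, 5), collapse = ", "),
         " have survey years not in the period order (e.g. ",
         records$survey_year[bad_year[1]], ")")
  }
  zf <- factor(records$zone_id, levels = zone_ids)
  pf <- factor(records$survey_year, levels = periods)
  n <- table(zf, pf)
  anem <- recode_anemia(records$anemia_level) == "anemic"
  O <- table(zf[anem], pf[anem])
  O <- matrix(as.integer(O), nrow = length(zone_ids),
              dimnames = list(zone_ids, as.character(periods)))
  n <- matrix(as.integer(n), nrow = length(zone_ids),
              dimnames = list(zone_ids, as.character(periods)))
  empty <- sum(n == 0)
  if (empty > 0) {
    warning(empty, " zone-period cell(s) received no records; counts set to 0")
  }
  structure(list(zone_ids = zone_ids, periods = periods, O = O, n = n),
            class = "count_table")
}

#' Construct a count table from pre-tabulated counts
#'
#' @param df Data frame with columns `zone_id`, `period`, `O`, `n`.
#' @param zone_ids,periods Optional orders; default the order of appearance.
#' @return A `count_table`.
#' @export
count_table <- function(df, zone_ids = unique(df$zone_id), periods = unique(df$period)) {
  O <- matrix(0L, length(zone_ids), length(periods),
              dimnames = list(zone_ids, as.character(periods)))
  n <- O
  i <- match(df$zone_id, zone_ids)
  k <- match(df$period, periods)
  if (anyNA(i) || anyNA(k)) stop("count rows outside the declared zone/period orders")
  O[cbind(i, k)] <- as.integer(df$O)
  n[cbind(i, k)] <- as.integer(df$n)
  if (any(O > n)) stop("observed counts exceed denominators")
  structure(list(zone_ids = zone_ids, periods = periods, O = O, n = n),
            class = "count_table")
}

#' Descriptive frequency table by survey period
#'
#' Counts and percentages per category of every categorical variable, by
#' period and overall; percentages are against non-missing totals and rounded
#' to 2 decimals.
#'
#' @param records Data frame of individual records.
#' @param variables Character vector of columns to summarise; default all
#'   known categorical record variables present in `records`.
#' @return Long data frame with columns `variable`, `category`, `period`
#'   (`"overall"` included), `count`, `percent`.
#' @export
descriptive_table <- function(records, variables = intersect(names(record_domains), names(records))) {
  stopifnot(nrow(records) > 0)
  periods <- sort(unique(records$survey_year))
  out <- list()
  for (v in variables) {
    lev <- record_domains[[v]]
    x <- records[[v]]
    if (is.null(lev)) lev <- sort(unique(stats::na.omit(x)))
    for (p in c(as.list(periods), list("overall"))) {
      sel <- if (identical(p, "overall")) !is.na(x) else records$survey_year == p & !is.na(x)
      cnt <- table(factor(x[sel], levels = lev))
      tot <- sum(cnt)
      out[[length(out) + 1L]] <- data.frame(
        variable = v, category = lev, period = as.character(p),
        count = as.integer(cnt),
        percent = if (tot > 0) round(100 * as.integer(cnt) / tot, 2) else 0,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

# Quartile assignment from a numeric score: 1 + number of empirical quartile
# cuts strictly below the value, so cut-straddling ties share the lower
# quartile.
assign_quartiles <- function(score) {
  cuts <- stats::quantile(score, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(score)) == 1) {
    warning("all proportions equal; every zone assigned quartile 1")
    return(rep(1L, length(score)))
  }
  1L + vapply(score, function(s) sum(s > cuts), integer(1))
}

quartile_prop <- function(records, variable) {
  switch(variable,
    education = records$maternal_education != "none",
    ses = records$wealth_quintile %in% c("richer", "richest"),
    maternal_anemia = records$maternal_anemia != "non-anemic",
    stop("unknown quartile variable: ", variable))
}

#' Zone-level quartile covariates
#'
#' For each zone (and, by default, each period) the proportion of mothers with
#' any education, with better socio-economic status (richer/richest wealth
#' quintile) and with any anemia is computed, and zones are cut at the
#' empirical 25/50/75 percentiles into quartile categories 1-4. Quartile 1 is
#' the reference: high education, high socio-economic status, low maternal
#' anemia. The design encoding carries indicator columns for quartiles 2-4 of
#' each variable.
#'
#' @param records Data frame of individual records.
#' @param zone_ids,periods Zone and period orders.
#' @param per_period Compute quartiles within each period (default) or pooled
#'   over periods (same category in every period).
#' @return A `zone_covariates`: list with `zone_ids`, `periods`, integer
#'   quartile matrices `edu_q`, `ses_q`, `manem_q` (zones x periods) and a
#'   3-d design array `X` (zones x periods x 9 indicators).
#' @export
quartile_covariates <- function(records, zone_ids, periods, per_period = TRUE) {
  if (length(zone_ids) < 4) stop("need at least 4 zones for quartile covariates")
  vars <- c(education = "education", ses = "ses", maternal_anemia = "maternal_anemia")
  # proportion matrices zones x periods (pooled: recycled across periods)
  qs <- list()
  for (v in vars) {
    ok <- quartile_prop(records, v)
    keep <- !is.na(ok)
    zf <- factor(records$zone_id[keep], levels = zone_ids)
    pf <- factor(records$survey_year[keep], levels = periods)
    if (per_period) {
      num <- tapply(ok[keep], list(zf, pf), sum)
      den <- tapply(rep(1, sum(keep)), list(zf, pf), sum)
      p <- num / den
      q <- apply(p, 2, function(col) {
        col[is.na(col)] <- mean(col, na.rm = TRUE)
        assign_quartiles(quartile_score(col, v))
      })
    } else {
      num <- tapply(ok[keep], zf, sum)
      den <- tapply(rep(1, sum(keep)), zf, sum)
      p <- num / den
      p[is.na(p)] <- mean(p, na.rm = TRUE)
      q <- matrix(assign_quartiles(quartile_score(p, v)),
                  nrow = length(zone_ids), ncol = length(periods))
    }
    dimnames(q) <- list(zone_ids, as.character(periods))
    qs[[v]] <- q
  }
  zone_covariates(zone_ids, periods,
                  edu_q = qs$education, ses_q = qs$ses, manem_q = qs$maternal_anemia)
}

# Direction handling: education and SES rank descending (high proportion ->
# quartile 1), maternal anemia ascending (low proportion -> quartile 1).
quartile_score <- function(p, variable) if (variable == "maternal_anemia") p else -p

#' Assemble zone covariates from quartile matrices
#'
#' @param zone_ids,periods Zone and period orders.
#' @param edu_q,ses_q,manem_q Integer matrices (zones x periods) of quartile
#'   categories 1-4 for low maternal education, low socio-economic status and
#'   maternal anemia.
#' @return A `zone_covariates` object with the indicator design array `X`.
#' @export
zone_covariates <- function(zone_ids, periods, edu_q, ses_q, manem_q) {
  stopifnot(all(edu_q %in% 1:4), all(ses_q %in% 1:4), all(manem_q %in% 1:4))
  coefs <- c(paste0("edu_q", 2:4), paste0("ses_q", 2:4), paste0("manem_q", 2:4))
  X <- array(0, dim = c(length(zone_ids), length(periods), 9),
             dimnames = list(zone_ids, as.character(periods), coefs))
  for (q in 2:4) {
    X[, , paste0("edu_q", q)] <- (edu_q == q) * 1
    X[, , paste0("ses_q", q)] <- (ses_q == q) * 1
    X[, , paste0("manem_q", q)] <- (manem_q == q) * 1
  }
  structure(list(zone_ids = zone_ids, periods = periods,
                 edu_q = edu_q, ses_q = ses_q, manem_q = manem_q, X = X),
            class = "zone_covariates")
}

#' @export
as.data.frame.zone_covariates <- function(x, ...) {
  grid <- expand.grid(zone_id = x$zone_ids, period = x$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$edu_q <- as.vector(x$edu_q)
  grid$ses_q <- as.vector(x$ses_q)
  grid$manem_q <- as.vector(x$manem_q)
  grid
}

#' @export
as.data.frame.count_table <- function(x, ...) {
  grid <- expand.grid(zone_id = x$zone_ids, period = x$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$O <- as.vector(x$O)
  grid$n <- as.vector(x$n)
  grid
}
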