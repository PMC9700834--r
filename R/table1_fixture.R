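# Printed per-period one-way margins of the descriptive table the fixture
# reproduces. Columns: 2005, 2011, 2016.
table1_margins <- list(
  anemia_level = list(
    severe = c(150, 291, 295), moderate = c(943, 2006, 2451),
    mild = c(723, 1739, 1795), "non-anemic" = c(1480, 4064, 3002)),
  maternal_age_group = list(
    "15-19" = c(129, 285, 223), "20-24" = c(617, 1543, 1493),
    "25-29" = c(965, 2546, 2282), "30-34" = c(683, 1719, 1201),
    "35-39" = c(547, 1291, 1711), "40-44" = c(250, 528, 485),
    "45-49" = c(105, 188, 148)),
  residence = list(urban = c(360, 1232, 1299), rural = c(2936, 6868, 6244)),
  region = list(
    Tigray = c(385, 946, 797), Afar = c(162, 768, 725),
    Amhara = c(442, 912, 741), Oromia = c(702, 1290, 1151),
    Somalia = c(163, 601, 999), Benishangul = c(255, 711, 649),
    SNNPRs = c(633, 1191, 968), Gambella = c(162, 558, 497),
    Harari = c(156, 401, 367), "Addis Ababa" = c(100, 248, 302),
    "Dire Dawa" = c(136, 474, 347)),
  maternal_education = list(
    none = c(2541, 5721, 4897), primary = c(556, 2022, 1927),
    secondary = c(182, 239, 479), higher = c(17, 118, 240)),
  wealth_quintile = list(
    poorest = c(856, 2514, 2767), poorer = c(628, 1521, 1341),
    middle = c(645, 1334, 1114), richer = c(590, 1356, 941),
    richest = c(577, 1375, 1380)),
  sex = list(male = c(1657, 4134, 3869), female = c(1639, 3966, 3674)),
  birth_weight_class = list(
    "<=2.5kg" = c(2400, 5607, 5501), ">2.5kg" = c(896, 2493, 2042)),
  birth_order_class = list(
    "1-3" = c(1551, 4084, 3870), "4-6" = c(1069, 2608, 2437),
    ">6" = c(676, 1408, 1236)),
  maternal_anemia = list(
    severe = c(48, 84, 121), moderate = c(304, 485, 730),
    mild = c(652, 1341, 1758), "non-anemic" = c(2292, 6191, 4830))
)

#' Synthetic individual records with exact descriptive-table margins
#'
#' Builds 18,939 synthetic child records (3,296 / 8,100 / 7,543 for the 2005,
#' 2011 and 2016 survey rounds) whose per-period one-way margins for every
#' categorical variable reproduce the published descriptive counts exactly.
#' The joint structure is product-of-margins: within each period every
#' variable's category vector is permuted independently, so cross-variable
#' associations are synthetic and carry no information. Zone ids cycle
#' through `zone_ids`.
#'
#' @param zone_ids Zone labels to cycle over (default `Z1`..`Z74`).
#' @return Data frame of individual records (one row per child).
#' @export
table1_fixture <- function(zone_ids = paste0("Z", 1:74)) {
  periods <- c(2005, 2011, 2016)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(20050216)
  per_period <- lapply(seq_along(periods), function(k) {
    nk <- sum(vapply(table1_margins$anemia_level, `[`, numeric(1), k))
    cols <- lapply(table1_margins, function(var) {
      cnt <- vapply(var, `[`, numeric(1), k)
      v <- rep(names(var), cnt)
      # some published margins do not sum to the survey n: shortfalls are
      # missing values, a single-record overflow is trimmed from the largest
      # category
      if (length(v) > nk) {
        drop_cat <- names(which.max(cnt))
        v <- v[-utils::tail(which(v == drop_cat), length(v) - nk)]
      }
      if (length(v) < nk) v <- c(v, rep(NA_character_, nk - length(v)))
      sample(v)
    })
    df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- names(table1_margins)
    df$survey_year <- periods[k]
    df$zone_id <- rep_len(zone_ids, nk)
    df
  })
  out <- do.call(rbind, per_period)
  rownames(out) <- NULL
  out
}
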