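test_that("anemia recode collapses mild/moderate/severe to anemic", {
  expect_equal(recode_anemia("mild"), "anemic")
  expect_equal(recode_anemia("severe"), "anemic")
  expect_equal(recode_anemia("moderate"), "anemic")
  expect_equal(recode_anemia("non-anemic"), "non-anemic")
  expect_error(recode_anemia("borderline"), "unknown anemia level")
})

test_that("tabulate_counts counts anemic children per zone-period", {
  recs <- data.frame(
    survey_year = 2011, zone_id = "A",
    anemia_level = c(rep("mild", 2), "severe", "moderate", rep("non-anemic", 6)))
  C <- suppressWarnings(tabulate_counts(recs, c("A", "B"), c(2005, 2011)))
  expect_equal(C$O["A", "2011"], 4L)
  expect_equal(C$n["A", "2011"], 10L)
  expect_equal(sum(C$n), 10L)
  expect_true(all(C$O <= C$n))

  expect_error(tabulate_counts(transform(recs, zone_id = "Z?"), c("A"), 2011),
               "zone ids not in the zone order")
  expect_error(tabulate_counts(recs, c("A"), 2005), "survey years not in")
})

test_that("empty cells yield zero counts with a warning", {
  recs <- data.frame(survey_year = 2005, zone_id = "A", anemia_level = "mild")
  expect_warning(C <- tabulate_counts(recs, c("A", "B"), c(2005, 2011)),
                 "received no records")
  expect_equal(unname(C$O["B", ]), c(0L, 0L))
})

test_that("descriptive percentages sum to 100 within rounding per variable-period", {
  recs <- small_sim()$records
  tab <- descriptive_table(recs)
  sums <- tapply(tab$percent, list(tab$variable, tab$period), sum)
  expect_true(all(abs(sums - 100) <= 0.05))
})

test_that("a single record makes its category 100% and the rest 0", {
  rec <- data.frame(survey_year = 2016, zone_id = "A", anemia_level = "mild",
                    residence = "urban")
  tab <- descriptive_table(rec, variables = "residence")
  expect_equal(tab$percent[tab$category == "urban" & tab$period == "overall"], 100)
  expect_equal(tab$percent[tab$category == "rural" & tab$period == "overall"], 0)
})

make_prop_records <- function(props, var = "education", n_per_zone = 10, year = 2011) {
  do.call(rbind, lapply(seq_along(props), function(i) {
    k <- round(props[i] * n_per_zone)
    base <- data.frame(
      survey_year = year, zone_id = sprintf("Z%02d", i),
      anemia_level = "mild",
      maternal_education = "none", wealth_quintile = "middle",
      maternal_anemia = "non-anemic")
    recs <- base[rep(1, n_per_zone), ]
    hit <- seq_len(n_per_zone) <= k
    if (var == "education") recs$maternal_education[hit] <- "primary"
    if (var == "ses") recs$wealth_quintile[hit] <- "richest"
    if (var == "maternal_anemia") recs$maternal_anemia[hit] <- "moderate"
    recs
  }))
}

test_that("education quartiles rank high-education zones as category 1", {
  recs <- make_prop_records(seq(0.8, 0.1, by = -0.1), "education")
  X <- quartile_covariates(recs, sprintf("Z%02d", 1:8), 2011)
  expect_equal(unname(X$edu_q[, 1]), c(1, 1, 2, 2, 3, 3, 4, 4))
})

test_that("maternal-anemia quartiles rank low-anemia zones as category 1", {
  recs <- make_prop_records(seq(0.1, 0.8, by = 0.1), "maternal_anemia")
  X <- quartile_covariates(recs, sprintf("Z%02d", 1:8), 2011)
  expect_equal(unname(X$manem_q[, 1]), c(1, 1, 2, 2, 3, 3, 4, 4))
})

test_that("ties straddling a quartile cut share the lower quartile", {
  props <- c(0.2, 0.4, 0.4, 0.6, 0.8)
  recs <- make_prop_records(props, "maternal_anemia")
  X <- quartile_covariates(recs, sprintf("Z%02d", 1:5), 2011)
  # brute-force oracle: independent type-7 percentile computation + strict cuts
  sorted <- sort(props)
  type7 <- function(q) {
    h <- (length(sorted) - 1) * q + 1
    lo <- floor(h)
    sorted[lo] + (h - lo) * (sorted[min(lo + 1, length(sorted))] - sorted[lo])
  }
  cuts <- c(type7(0.25), type7(0.5), type7(0.75))
  oracle <- 1L + vapply(props, function(s) sum(s > cuts), integer(1))
  expect_equal(unname(X$manem_q[, 1]), oracle)
  # the tied pair lands in the same (lower) quartile
  expect_equal(X$manem_q[2, 1], X$manem_q[3, 1])
})

test_that("quartile assignment is invariant to zone input order", {
  sim <- small_sim()
  ids <- sim$counts$zone_ids
  X1 <- quartile_covariates(sim$records, ids, sim$counts$periods)
  set.seed(3)
  perm <- sample(length(ids))
  X2 <- quartile_covariates(sim$records, ids[perm], sim$counts$periods)
  expect_equal(X2$edu_q[ids, ], X1$edu_q[ids, ])
  expect_equal(X2$manem_q[ids, ], X1$manem_q[ids, ])
})

test_that("quartile covariates need at least 4 zones and handle degenerate input", {
  recs <- make_prop_records(c(0.5, 0.5, 0.5), "education")
  expect_error(quartile_covariates(recs, sprintf("Z%02d", 1:3), 2011),
               "at least 4 zones")
  recs4 <- make_prop_records(rep(0.5, 4), "education")
  expect_warning(X <- quartile_covariates(recs4, sprintf("Z%02d", 1:4), 2011),
                 "all proportions equal")
  expect_true(all(X$edu_q == 1))
})

test_that("the design array encodes quartile 2-4 indicators with quartile 1 reference", {
  sim <- small_sim()
  X <- sim$covariates
  expect_equal(dim(X$X)[3], 9)
  expect_equal(unname(X$X[, , "edu_q3"]), unname((X$edu_q == 3) * 1))
  # per zone-period at most one indicator per variable
  per_var <- X$X[, , 1:3]
  expect_true(all(apply(per_var, c(1, 2), sum) <= 1))
})
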