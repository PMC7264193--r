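test_that("HB length derivation subtracts tail from total and flags impossible anatomy", {
  r <- make_records(3,
                    total_length = c(160, 150, 60),
                    tail_length = c(70, NA, 70))
  out <- derive_hb_length(r)
  expect_equal(out$hb_length, c(90, NA, NA))
  expect_match(out$filter_flags[3], "negative_hb")
  expect_false(grepl("negative_hb", out$filter_flags[1]))
})

test_that("mass floor removes strictly-below-floor records and keeps missing masses", {
  r <- make_records(4, body_mass = c(8.9, 9.0, 9.1, NA))
  res <- filter_mass_floor(r, floor = 9)
  expect_equal(res$n_removed, 1L)
  expect_setequal(res$records$body_mass[!is.na(res$records$body_mass)],
                  c(9.0, 9.1))
  expect_true(any(is.na(res$records$body_mass)))  # HB-only record retained
})

test_that("only records labelled juvenile are filtered; unknown stages survive", {
  r <- make_records(3, life_stage = c("juvenile", "unknown", "adult"))
  res <- filter_lifestage(r, include_juveniles = FALSE)
  expect_equal(res$n_removed, 1L)
  expect_setequal(res$records$life_stage, c("unknown", "adult"))
  expect_equal(filter_lifestage(r, include_juveniles = TRUE)$n_removed, 0L)
})

test_that("date filter drops 1-January, pre-1895, incomplete, and impossible dates", {
  r <- make_records(6,
                    year = c(1950L, 1894L, 1950L, 1950L, 1950L, 2000L),
                    month = c(1L, 6L, 2L, NA, 7L, 2L),
                    day = c(1L, 15L, 30L, 15L, 4L, 29L))
  res <- filter_dates(r)
  # survivors: 1950-07-04 and 2000-02-29 (a real leap day)
  expect_equal(res$n_removed, 4L)
  expect_setequal(paste(res$records$year, res$records$month, res$records$day),
                  c("1950 7 4", "2000 2 29"))
})

test_that("sex filter is case-insensitive and rejects ambiguous tokens", {
  r <- make_records(6, sex = c("female?", "Male", "", "undetermined",
                               "FEMALE", "male"))
  res <- filter_sex(r)
  expect_equal(res$n_removed, 3L)
  expect_setequal(res$records$sex, c("male", "female"))
})

test_that("season assignment matches the equinox/solstice boundary table on all 366 days", {
  days <- expand.grid(month = 1:12, day = 1:31)
  days <- days[days$day <= days_in_month(2020L, days$month), ]
  expect_equal(nrow(days), 366L)
  got <- assign_season(days$month, days$day)
  expect_equal(got, unname(season_oracle(days$month, days$day)))
  # named boundary cases
  expect_equal(assign_season(7, 4), "Summer")
  expect_equal(assign_season(9, 22), "Fall")
  expect_equal(assign_season(3, 19), "Winter")
  expect_equal(assign_season(3, 20), "Spring")
  expect_equal(assign_season(12, 21), "Winter")
  expect_error(assign_season(2, NA))
})

test_that("decade binning is anchored at 1895 with a truncated 13th bin", {
  expect_equal(assign_decade(1895), 1L)
  expect_equal(assign_decade(1904), 1L)
  expect_equal(assign_decade(1905), 2L)
  expect_equal(assign_decade(1948), 6L)
  expect_equal(assign_decade(2014), 12L)
  expect_equal(assign_decade(c(2015, 2019)), c(13L, 13L))
  expect_error(assign_decade(1894))
  # every year 1895-2019 lands in one of exactly 13 bins of width <= 10
  bins <- assign_decade(1895:2019)
  expect_equal(sort(unique(bins)), 1:13)
  spans <- tapply(1895:2019, bins, function(y) diff(range(y)) + 1)
  expect_true(all(spans[1:12] == 10))
  expect_equal(unname(spans[13]), 5)
  expect_equal(decade_label(13L), "2015-2019")
  expect_equal(decade_label(1L), "1895-1904")
})

test_that("outlier pass removes any-measurement outliers in a single pass", {
  # 30 typical masses and one gross error: z = (100 - mean)/sd > 3
  r <- make_records(31, body_mass = c(rep(10, 30), 100),
                    total_length = NA_real_, tail_length = NA_real_)
  res <- flag_outliers(r)
  expect_equal(res$n_removed, 1L)
  expect_equal(res$removed$body_mass, 100)

  # the sample-SD convention means a single extreme value among few
  # records can dominate the SD and escape the 3-SD rule
  r5 <- make_records(5, body_mass = c(10, 10, 10, 10, 100),
                     total_length = NA_real_, tail_length = NA_real_)
  z <- abs(100 - mean(r5$body_mass)) / sd(r5$body_mass)
  expect_lt(z, 3)  # hand check: the rule cannot flag it
  expect_equal(flag_outliers(r5)$n_removed, 0L)

  # identical values: SD = 0 branch, nothing removed
  expect_equal(flag_outliers(make_records(10))$n_removed, 0L)

  # outlying in tail length only is still removed
  r2 <- make_records(31, tail_length = c(rep(65, 30), 300))
  res2 <- flag_outliers(r2)
  expect_equal(res2$n_removed, 1L)
  expect_equal(res2$removed$tail_length, 300)
})

test_that("pipeline audit is conserved and chains across steps", {
  b <- cached_bundle(101, 6000)
  out <- run_pipeline(b$records, list(temporal = TRUE))
  a <- out$audit
  expect_true(all(a$n_out == a$n_in - a$n_removed))
  # shared steps chain: out of step i = in of step i+1
  shared <- a[a$step %in% c("coordinates", "dates", "sex", "lifestage"), ]
  expect_equal(shared$n_in[-1], shared$n_out[-nrow(shared)])
  expect_equal(sum(!is.na(out$mass$body_mass)), nrow(out$mass))
  expect_true(all(out$mass$body_mass >= 9))
  expect_true(all(out$mass$year >= 1945))
  expect_true(all(out$mass$sex %in% c("female", "male")))
  expect_true(all(out$hb$hb_length == out$hb$total_length - out$hb$tail_length))
})

test_that("pipeline on empty input returns empty outputs and an all-zero audit", {
  out <- run_pipeline(make_records(0))
  expect_equal(nrow(out$mass), 0L)
  expect_equal(nrow(out$hb), 0L)
  expect_true(all(out$audit$n_removed == 0L))
})

test_that("NEON toggle changes the HB dataset by exactly the NEON record count", {
  b <- cached_bundle(101, 6000)
  with_neon <- run_pipeline(b$records, list(include_neon = TRUE))
  without <- run_pipeline(b$records, list(include_neon = FALSE))
  n_neon_hb <- sum(with_neon$hb$source == "NEON")
  expect_gt(n_neon_hb, 0)
  expect_equal(nrow(with_neon$hb) - nrow(without$hb), n_neon_hb)
})

test_that("unknown config keys are rejected", {
  expect_error(run_pipeline(make_records(1), list(bogus = 1)), "unknown config")
})

test_that("pipeline is idempotent apart from the documented outlier semantics", {
  b <- cached_bundle(101, 6000)
  once <- run_pipeline(b$records, list())
  # rerun on the mass output: every non-outlier step removes nothing
  again <- run_pipeline(once$mass, list())
  a2 <- again$audit
  non_outlier <- a2[!grepl("outlier", a2$step), ]
  expect_true(all(non_outlier$n_removed == 0L))
})
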