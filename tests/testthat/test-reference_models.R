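test_that("LMS z-score matches closed forms and is continuous at L = 0", {
  expect_equal(lms_zscore(15, L = 1, M = 15, S = 0.1), 0)
  expect_equal(lms_zscore(16.5, L = 1, M = 15, S = 0.1), 1.0)
  # direct evaluation of ((20/15)^-1.5 - 1)/(-1.5 * 0.12), frozen
  expect_equal(lms_zscore(20, L = -1.5, M = 15, S = 0.12), 1.947116,
               tolerance = 1e-6)
  # L -> 0 limit equals the logarithmic branch
  expect_equal(lms_zscore(18, L = 1e-7, M = 15, S = 0.1),
               lms_zscore(18, L = 0, M = 15, S = 0.1), tolerance = 1e-6)
  expect_error(lms_zscore(-1, 1, 15, 0.1), class = "invalid_parameter")
  expect_error(lms_zscore(15, 1, 0, 0.1), class = "invalid_parameter")
  expect_error(lms_zscore(15, 1, 15, -0.2), class = "invalid_parameter")
})

test_that("LMS z-score is strictly increasing in x and zero at the median", {
  for (L in c(-1.5, -0.5, 0, 0.7, 1, 2)) {
    x <- seq(5, 40, by = 0.5)
    z <- lms_zscore(x, L, M = 15, S = 0.12)
    expect_true(all(diff(z) > 0))
    expect_equal(lms_zscore(15, L, 15, 0.12), 0)
  }
})

test_that("percentile_from_z maps the normal CDF onto (0, 100)", {
  expect_equal(percentile_from_z(0), 50)
  expect_equal(percentile_from_z(1.6449), 95.0, tolerance = 1e-4)
  expect_equal(percentile_from_z(-1.6449), 100 - percentile_from_z(1.6449))
  z <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(percentile_from_z(z)) > 0))
  expect_error(percentile_from_z(Inf), class = "invalid_parameter")
})

test_that("height percentile composes interpolation, z-score and CDF", {
  ref <- tiny_growth_ref()
  # at the interpolated median the percentile is exactly 50
  expect_equal(height_percentile("male", 96, 120, ref), 50)
  expect_equal(height_percentile("female", 150, 120 + 0.6 * (150 - 96), ref), 50)
  # M = 120, S = 0.05 at 96 months; height 126 is z = 1 -> 84.13th
  expect_equal(height_percentile("male", 96, 126, ref),
               100 * pnorm(1), tolerance = 1e-9)
  expect_error(height_percentile("male", 6, 70, ref), class = "out_of_range")
  expect_error(height_percentile("male", 400, 190, ref), class = "out_of_range")
})

test_that("BP table lookup interpolates across the height grid with clamping", {
  tab <- tiny_bp_table()
  # grid point returns the raw cell exactly, for every column
  for (h in c(5, 10, 25, 50, 75, 90, 95)) {
    expect_identical(
      bp_percentile_value(tab, "fourth_2004", "male", 10, h, "SBP", 90), 110)
  }
  # midpoint between columns with values 108 and 110 -> 109
  tab2 <- tiny_bp_table()
  sel <- tab2$metric == "SBP" & tab2$bp_percentile == 90
  tab2$value[sel] <- 108 + 2 * (tab2$height_percentile[sel] >= 75)
  tab2 <- validate_bp_reference(tab2)
  expect_equal(
    bp_percentile_value(tab2, "fourth_2004", "male", 10, 62.5, "SBP", 90), 109)
  # clamping below and above the grid
  expect_equal(bp_percentile_value(tab2, "fourth_2004", "male", 10, 1, "SBP", 90),
               bp_percentile_value(tab2, "fourth_2004", "male", 10, 5, "SBP", 90))
  expect_equal(bp_percentile_value(tab2, "fourth_2004", "male", 10, 99, "SBP", 90),
               bp_percentile_value(tab2, "fourth_2004", "male", 10, 95, "SBP", 90))
  expect_error(bp_percentile_value(tab, "fourth_2004", "male", 25, 50, "SBP", 90),
               class = "table_incomplete")
})

test_that("table validation rejects non-monotone reference values", {
  tab <- tiny_bp_table()
  bad <- tab
  i <- which(bad$bp_percentile == 95 & bad$metric == "SBP")[1]
  bad$value[i] <- 100 # below the 90th value
  expect_error(validate_bp_reference(bad), class = "table_error")
  bad2 <- tab
  j <- which(bad2$height_percentile == 95 & bad2$metric == "SBP" &
               bad2$bp_percentile == 90)[1]
  bad2$value[j] <- 90
  expect_error(validate_bp_reference(bad2), class = "table_error")
})

test_that("threshold resolution reproduces the guideline rule set", {
  tab <- tiny_bp_table() # p90 110/70, p95 115/74
  # AAP static band at >= 13 y: 120/80 elevated, 130/80 hypertension,
  # invariant to sex and height
  for (s in c("male", "female")) for (h in c(3, 25, 50, 97)) {
    ts <- resolve_thresholds("aap_2017", s, 15, h, tab)
    expect_equal(ts$elevated_sbp, 120); expect_equal(ts$elevated_dbp, 80)
    expect_equal(ts$htn_sbp, 130); expect_equal(ts$htn_dbp, 80)
    expect_equal(ts$provenance, "static")
  }
  # adult rule at 18-20 under both guidelines
  for (g in GUIDELINES) {
    ts <- resolve_thresholds(g, "male", 18, 50, tab)
    expect_equal(ts$htn_sbp, 140); expect_equal(ts$htn_dbp, 90)
    expect_equal(ts$elevated_sbp, 120); expect_equal(ts$elevated_dbp, 80)
  }
  # 2004 at age 10: hypertension = 95th percentile + 5
  ts <- resolve_thresholds("fourth_2004", "male", 10, 50, tab)
  expect_equal(ts$htn_sbp, 120) # 115 + 5
  expect_equal(ts$htn_dbp, 79)  # 74 + 5
  expect_equal(ts$elevated_sbp, 110) # min(110, 120)
  expect_equal(ts$elevated_dbp, 70)
  # the 120/80 static floor binds when the 90th percentile exceeds it
  hightab <- tiny_bp_table(p90s = 125, p95s = 129, p90d = 82, p95d = 85)
  ts2 <- resolve_thresholds("fourth_2004", "male", 10, 50, hightab)
  expect_equal(ts2$elevated_sbp, 120)
  expect_equal(ts2$elevated_dbp, 80)
  # AAP 1-12: hypertension = min(95th, 130/80)
  ts3 <- resolve_thresholds("aap_2017", "male", 10, 50, hightab)
  expect_equal(ts3$htn_sbp, 129)
  expect_equal(ts3$htn_dbp, 80)
  expect_error(resolve_thresholds("aap_2017", "male", 0, 50, tab),
               class = "invalid_parameter")
})

test_that("every resolved threshold set keeps elevated at or below hypertension", {
  tab <- gen_bp_reference(1)
  set.seed(11)
  ctx <- data.frame(
    guideline = sample(GUIDELINES, 200, TRUE),
    sex = sample(c("male", "female"), 200, TRUE),
    age_years = sample(1:20, 200, TRUE),
    height_pct = runif(200, 1, 99), stringsAsFactors = FALSE
  )
  th <- pedhtn:::resolve_thresholds_batch(ctx, tab)
  expect_true(all(th$elevated_sbp <= th$htn_sbp))
  expect_true(all(th$elevated_dbp <= th$htn_dbp))
  # batch path agrees with the scalar resolver
  for (i in sample(200, 10)) {
    ts <- resolve_thresholds(ctx$guideline[i], ctx$sex[i], ctx$age_years[i],
                             ctx$height_pct[i], tab)
    expect_equal(unlist(th[i, ]), unlist(ts[1, 1:4]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
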