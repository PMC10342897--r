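aap15 <- function() resolve_thresholds("aap_2017", "male", 15, 50, tiny_bp_table())

test_that("visit classification applies and/or logic with HTN precedence", {
  ts <- aap15()
  expect_equal(classify_visit(130, 70, ts), "HTN")
  expect_equal(classify_visit(119, 79, ts), "NORMAL")
  expect_equal(classify_visit(125, 75, ts), "ELEVATED")
  expect_equal(classify_visit(110, 80, ts), "HTN")      # DBP alone triggers
  expect_equal(classify_visit(120, 60, ts), "ELEVATED") # SBP alone
  # vectorized
  expect_equal(classify_visit(c(130, 119, 125), c(70, 79, 75), ts),
               c("HTN", "NORMAL", "ELEVATED"))
})

test_that("person-year rule needs three qualifying occasions of one metric", {
  tab <- tiny_bp_table()
  ref <- tiny_growth_ref()
  cls <- function(sbp, dbp, offs = seq_along(sbp) * 20) {
    classify_person_year(age_year_visits(15, offs, sbp, dbp, growth_ref = ref),
                         "aap_2017", tab, ref)
  }
  # three SBP readings at/above 130 -> hypertensive person-year
  r <- cls(c(135, 132, 131), c(70, 70, 70))
  expect_equal(r$category, "HTN")
  expect_equal(r$n_sbp_htn, 3)
  # two HTN-level + one elevated-level: HTN count 2 < 3, elevated count 3
  r2 <- cls(c(135, 135, 125), c(70, 70, 70))
  expect_equal(r2$category, "ELEVATED")
  expect_equal(r2$n_sbp_htn, 2)
  expect_equal(r2$n_sbp_elev, 3)
  # two occasions only: ineligible, never classified
  r3 <- cls(c(135, 135), c(70, 70))
  expect_false(r3$eligible)
  expect_equal(r3$category, "NORMAL")
  # mixed pattern: 2 high-SBP + 2 high-DBP occasions does not qualify
  r4 <- cls(c(135, 135, 100, 100), c(70, 70, 85, 85))
  expect_equal(r4$n_sbp_htn, 2)
  expect_equal(r4$n_dbp_htn, 2)
  expect_equal(r4$category, "NORMAL")
  # but 3 DBP alone does
  r5 <- cls(c(100, 100, 100), c(85, 82, 81))
  expect_equal(r5$category, "HTN")
})

test_that("same-date repeats collapse to a single occasion", {
  tab <- tiny_bp_table(); ref <- tiny_growth_ref()
  v <- age_year_visits(15, c(10, 10, 10, 40, 70), rep(135, 5), rep(70, 5),
                       growth_ref = ref)
  r <- classify_person_year(v, "aap_2017", tab, ref)
  expect_equal(r$n_occasions, 3)
  expect_equal(r$category, "HTN")
  # with only two distinct dates the person-year is ineligible
  v2 <- age_year_visits(15, c(10, 10, 40), rep(135, 3), rep(70, 3),
                        growth_ref = ref)
  expect_false(classify_person_year(v2, "aap_2017", tab, ref)$eligible)
})

test_that("occasion counts nest and hypertensive person-years imply elevated counts", {
  tab <- tiny_bp_table(); ref <- tiny_growth_ref()
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    v <- age_year_visits(15, sort(sample(0:364, n)),
                         round(runif(n, 100, 150)), round(runif(n, 55, 95)),
                         growth_ref = ref)
    r <- classify_person_year(v, "aap_2017", tab, ref)
    expect_gte(r$n_sbp_elev, r$n_sbp_htn)
    expect_gte(r$n_dbp_elev, r$n_dbp_htn)
    if (r$category == "HTN") {
      expect_true(max(r$n_sbp_elev, r$n_dbp_elev) >= 3)
    }
  }
})

test_that("raising any reading never lowers the visit or person-year category", {
  tab <- tiny_bp_table(); ref <- tiny_growth_ref()
  rank <- function(x) match(x, BP_CATEGORIES)
  set.seed(6)
  for (i in 1:15) {
    n <- 4
    sbp <- round(runif(n, 105, 140)); dbp <- round(runif(n, 60, 85))
    v <- age_year_visits(15, c(0, 40, 80, 120), sbp, dbp, growth_ref = ref)
    base <- classify_person_year(v, "aap_2017", tab, ref)
    j <- sample(n, 1)
    v2 <- v; v2$sbp[j] <- v2$sbp[j] + sample(1:20, 1)
    up <- classify_person_year(v2, "aap_2017", tab, ref)
    expect_gte(rank(up$category), rank(base$category))
  }
})

test_that("cohort classification windows person-years and flags discordance", {
  ref <- tiny_growth_ref()
  tab <- tiny_bp_table()
  # one person spanning ages 12-14 -> one row per age-year per guideline
  v <- rbind(age_year_visits(12, c(1, 50, 100), 100, 60, growth_ref = ref),
             age_year_visits(13, c(1, 50, 100), 100, 60, growth_ref = ref),
             age_year_visits(14, c(1, 50, 100), 100, 60, growth_ref = ref))
  py <- classify_cohort(v, tab, ref)
  expect_equal(nrow(py), 6)
  expect_equal(sort(unique(py$age_years)), c(12, 13, 14))
  # table where 2004's 95th + 5 = 133 exceeds the AAP static 130: readings
  # at 131 are hypertensive under AAP only
  tab2 <- tiny_bp_table(p90s = 124, p95s = 128)
  v2 <- age_year_visits(13, c(1, 50, 100), c(131, 131.5, 132), 70,
                        growth_ref = ref)
  py2 <- classify_cohort(v2, tab2, ref)
  expect_equal(py2$category[py2$guideline == "aap_2017"], "HTN")
  expect_equal(py2$category[py2$guideline == "fourth_2004"], "ELEVATED")
  # empty cohort
  expect_equal(nrow(classify_cohort(v[0, ], tab, ref)), 0)
  # unknown sex code is a row-level validation error
  vbad <- v; vbad$sex[2] <- "unknown"
  expect_error(classify_cohort(vbad, tab, ref), class = "validation_error")
})

test_that("guideline with pointwise lower thresholds classifies a superset", {
  ref <- tiny_growth_ref()
  tab <- gen_bp_reference(1, style = "aap_dominant")
  set.seed(9)
  sim <- gen_cohort(sim_config(n_persons = 150, age_range = c(8, 17),
                               bp_model = "ambient", condition_rates = 0,
                               missing_height_rate = 0, bp_outlier_rate = 0,
                               growth_outlier_rate = 0, seed = 9),
                    bp_tables = tab)
  py <- classify_cohort(sim$visits, tab, sim$growth_ref)
  key <- function(d) paste(d$person_id, d$age_years)
  htn04 <- key(py[py$guideline == "fourth_2004" & py$category == "HTN", ])
  htn17 <- key(py[py$guideline == "aap_2017" & py$category == "HTN", ])
  expect_true(all(htn04 %in% htn17))
})
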