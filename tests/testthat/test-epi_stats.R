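test_that("event rate rounds half-up per 1000 persons", {
  expect_equal(event_rate(1300, 218368), 5.95)
  expect_equal(event_rate(573, 255615), 2.24)
  expect_equal(event_rate(0, 1000), 0)
  expect_equal(event_rate(1, 800), 1.25)
  expect_equal(event_rate(5, 4000), 1.25)
  expect_error(event_rate(1, 0), class = "undefined_rate")
  expect_error(event_rate(10, 5), class = "invalid_parameter")
})

mk_py <- function(person_id, age_years, guideline, category,
                  eligible = TRUE, n_occasions = 3) {
  data.frame(person_id = person_id, age_years = age_years,
             guideline = guideline, n_occasions = n_occasions,
             eligible = eligible, n_sbp_htn = 0, n_dbp_htn = 0,
             n_sbp_elev = 0, n_dbp_elev = 0, category = category,
             stringsAsFactors = FALSE)
}

test_that("participants at risk count person-year units within the group", {
  py <- rbind(mk_py("A", 13, "aap_2017", "NORMAL"),
              mk_py("A", 14, "aap_2017", "NORMAL"),
              mk_py("A", 15, "aap_2017", "HTN"),
              mk_py("B", 10, "aap_2017", "NORMAL"))
  expect_equal(participants_at_risk(py, c(13, 17)), 3)
  expect_equal(participants_at_risk(py, c(8, 12)), 1)
  expect_equal(participants_at_risk(py[0, ], c(1, 7)), 0)
  # duplicated guideline rows count each unit once
  py2 <- rbind(py, mk_py(py$person_id, py$age_years, "fourth_2004", py$category))
  expect_equal(participants_at_risk(py2, c(13, 17)), 3)
  # 20 persons x 2 in-range age-years each
  big <- do.call(rbind, lapply(1:20, function(i)
    mk_py(paste0("P", i), c(9, 10), "aap_2017", "NORMAL")))
  expect_equal(participants_at_risk(big, c(8, 12)), 40)
  # ineligible person-years drop out of the eligible_only denominator
  py3 <- rbind(py, mk_py("C", 13, "aap_2017", "NORMAL", eligible = FALSE))
  expect_equal(participants_at_risk(py3, c(13, 17), "any_obp"), 4)
  expect_equal(participants_at_risk(py3, c(13, 17), "eligible_only"), 3)
})

test_that("annual rate uses calendar-year participants and overlapping cases", {
  ref <- tiny_growth_ref(); tab <- tiny_bp_table()
  v <- rbind(
    age_year_visits(15, c(1, 40, 80), c(135, 134, 133), 70, person_id = "H",
                    birth_date = as.Date("1997-03-01"), growth_ref = ref),
    age_year_visits(15, c(1, 40, 80), 100, 60, person_id = "N",
                    birth_date = as.Date("1997-03-01"), growth_ref = ref)
  )
  py <- classify_cohort(v, tab, ref)
  yr <- as.integer(format(v$visit_date[1], "%Y"))
  r <- annual_rate(py[py$guideline == "aap_2017", ], v, yr, "aap_2017")
  expect_equal(r$participants, 2)
  expect_equal(r$cases, 1)
  expect_equal(r$rate_per_1000, 500)
  expect_error(annual_rate(py, v, 1990, "aap_2017"), class = "undefined_rate")
  # all persons hypertensive -> 1000
  vh <- v[v$person_id == "H", ]
  pyh <- classify_cohort(vh, tab, ref)
  expect_equal(annual_rate(pyh, vh, yr, "aap_2017")$rate_per_1000, 1000)
})

test_that("Cohen's kappa matches hand arithmetic and degenerates correctly", {
  perfect <- cohens_kappa(50, 0, 0, 50)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$pct_agreement, 100)
  expect_equal(perfect$se, 0)
  indep <- cohens_kappa(10, 10, 10, 10)
  expect_equal(indep$kappa, 0)
  hand <- cohens_kappa(40, 5, 5, 50)
  expect_equal(hand$kappa, (0.9 - 0.505) / (1 - 0.505), tolerance = 1e-12)
  expect_equal(round_half_up(hand$kappa, 4), 0.798)
  expect_equal(hand$pct_agreement, 90)
  expect_true(hand$ci_low <= hand$kappa && hand$kappa <= hand$ci_high)
  expect_error(cohens_kappa(0, 0, 0, 0), class = "invalid_parameter")
  expect_error(cohens_kappa(100, 0, 0, 0), class = "kappa_undefined")
})

test_that("kappa is invariant under rater transposition; 1 iff diagonal", {
  set.seed(13)
  for (i in 1:25) {
    n <- as.vector(rmultinom(1, 200, runif(4, 0.05, 1)))
    a <- cohens_kappa(n[1], n[2], n[3], n[4])
    b <- cohens_kappa(n[1], n[3], n[2], n[4]) # transpose the 2x2
    expect_equal(a$kappa, b$kappa, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
    if (n[2] + n[3] > 0) expect_lt(a$kappa, 1)
  }
})

test_that("analytic kappa SE agrees with a multinomial bootstrap", {
  obs <- cohens_kappa(40, 5, 5, 50)
  set.seed(99)
  boot <- replicate(4000, {
    n <- as.vector(rmultinom(1, 100, c(40, 5, 5, 50) / 100))
    p <- n / 100
    po <- p[1] + p[4]
    pe <- (p[1] + p[2]) * (p[1] + p[3]) + (p[4] + p[2]) * (p[4] + p[3])
    (po - pe) / (1 - pe)
  })
  expect_equal(obs$se, sd(boot), tolerance = 0.08)
})

test_that("kappa interpretation bands follow the printed breaks", {
  expect_equal(kappa_band(0.85), "almost_perfect")
  expect_equal(kappa_band(0.20), "none")
  expect_equal(kappa_band(0.50), "moderate")
  expect_equal(kappa_band(0.204), "none")       # rounds to 0.20
  expect_equal(kappa_band(0.206), "fair")       # rounds to 0.21
  expect_equal(kappa_band(0.61), "substantial")
  expect_equal(kappa_band(-0.3), "none")
  expect_equal(kappa_band(1), "almost_perfect")
})

test_that("guideline agreement builds the 2x2 from aligned person-years", {
  both <- function(cat04, cat17, ids = paste0("P", seq_along(cat04))) {
    rbind(mk_py(ids, 10, "fourth_2004", cat04),
          mk_py(ids, 10, "aap_2017", cat17))
  }
  same <- both(c("HTN", "HTN", "NORMAL", "NORMAL"),
               c("HTN", "HTN", "NORMAL", "NORMAL"))
  ag <- guideline_agreement(same, c(8, 12))
  expect_equal(ag$kappa, 1)
  # AAP flags a strict superset: no 2004-only cases (n10 = 0)
  sup <- both(c("HTN", "NORMAL", "NORMAL", "NORMAL"),
              c("HTN", "HTN", "NORMAL", "NORMAL"))
  ag2 <- guideline_agreement(sup, c(8, 12))
  expect_equal(ag2$n10, 0)
  expect_equal(ag2$n01, 1)
  expect_error(guideline_agreement(same, c(13, 17)), class = "invalid_parameter")
  misaligned <- rbind(mk_py("A", 10, "fourth_2004", "HTN"),
                      mk_py("B", 10, "aap_2017", "HTN"))
  expect_error(guideline_agreement(misaligned, c(8, 12)), class = "alignment_error")
})

test_that("BMI categories follow the 5/85/95 percentile breaks", {
  ref <- tiny_growth_ref()
  # at 96 months BMI M = 17, S = 0.10, L = 1: bmi at percentile p is
  # M * (1 + qnorm(p/100) * S); height 120 fixes the weight
  w_at <- function(p) 17 * (1 + qnorm(p / 100) * 0.10) * 1.2^2
  cat_at <- function(p) bmi_category(w_at(p), 120, "male", 96, ref)
  expect_equal(cat_at(95), "obesity")
  expect_equal(cat_at(96), "obesity")
  expect_equal(cat_at(94.9), "overweight")
  expect_equal(cat_at(85), "overweight")
  expect_equal(cat_at(84.9), "normal")
  expect_equal(cat_at(50), "normal")
  expect_equal(cat_at(5), "normal")
  expect_equal(cat_at(4.9), "underweight")
  expect_error(bmi_category(-1, 120, "male", 96, ref), class = "invalid_parameter")
})

test_that("logistic odds ratios match the 2x2 cross-product for one covariate", {
  set.seed(17)
  x <- rbinom(600, 1, 0.4)
  y <- rbinom(600, 1, plogis(-1.2 + 0.9 * x))
  d <- data.frame(y = y, x = x, age_years = 10)
  fit <- logistic_or(d, "y", "x")
  tab <- table(x, y)
  or <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(fit$aOR, unname(or), tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$aOR && fit$aOR <= fit$ci_high)
  expect_error(logistic_or(data.frame(y = rep(1, 50), x = rnorm(50),
                                      age_years = 10), "y", "x"),
               class = "invalid_parameter")
  # complete separation is diagnosed, naming the covariate
  sep <- data.frame(y = rep(c(0, 1), each = 25),
                    x = rep(c(0, 1), each = 25), age_years = 10)
  err <- tryCatch(logistic_or(sep, "y", "x"), pedhtn_error = identity)
  expect_s3_class(err, "separation_error")
  expect_match(conditionMessage(err), "x")
})

test_that("null-covariate Wald intervals cover 1.0 at nominal rate", {
  set.seed(23)
  cover <- vapply(1:100, function(i) {
    x <- rnorm(500)
    y <- rbinom(500, 1, 0.15)
    f <- logistic_or(data.frame(y = y, x = x, age_years = 10), "y", "x")
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})
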