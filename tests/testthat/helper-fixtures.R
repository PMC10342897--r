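# In-code fixtures shared across the suite. All tables are tiny synthetic
# stand-ins built to make expected values derivable by hand.

# L = 1 growth reference: z = (x - M)/(M*S) in closed form.
# height M = 120 at 96 months, slope 0.6 cm/month; S = 0.05.
tiny_growth_ref <- function() {
  ages <- c(12, 96, 260)
  mk <- function(sex, measure, M, S) {
    data.frame(sex = sex, age_months = ages, measure = measure,
               L = 1, M = M, S = S, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("male", "female"), function(s) rbind(
    mk(s, "height_for_age", 120 + 0.6 * (ages - 96), 0.05),
    mk(s, "weight_for_age", 30 + 0.2 * (ages - 96), 0.10),
    mk(s, "bmi_for_age", 17 + 0.01 * (ages - 96), 0.10)
  )))
}

# Flat-in-height BP table with hand-chosen percentile values, both
# guidelines, all ages 1-17, both sexes.
tiny_bp_table <- function(p50s = 95, p90s = 110, p95s = 115,
                          p50d = 60, p90d = 70, p95d = 74) {
  grid <- expand.grid(
    guideline = GUIDELINES, sex = c("male", "female"), age_years = 1:17,
    height_percentile = c(5, 10, 25, 50, 75, 90, 95),
    metric = c("SBP", "DBP"), bp_percentile = c(50, 90, 95),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  v <- matrix(c(p50s, p90s, p95s, p50d, p90d, p95d), nrow = 2, byrow = TRUE,
              dimnames = list(c("SBP", "DBP"), c("50", "90", "95")))
  grid$value <- v[cbind(grid$metric, as.character(grid$bp_percentile))]
  validate_bp_reference(grid)
}

# visit-record constructor with sane defaults
visit_rows <- function(person_id = "P1", visit_date, sex = "male",
                       birth_date = "2000-06-15", sbp = 100, dbp = 60,
                       height_cm = 120, weight_kg = 30,
                       setting = "outpatient") {
  data.frame(person_id = person_id, visit_date = as.Date(visit_date),
             sex = sex, birth_date = as.Date(birth_date), sbp = sbp,
             dbp = dbp, height_cm = height_cm, weight_kg = weight_kg,
             setting = setting, stringsAsFactors = FALSE)
}

# visits for one person at a given exact age (years + offset days), with
# height at the reference median so the height percentile is exactly 50
age_year_visits <- function(age_years, day_offsets, sbp, dbp,
                            person_id = "P1", sex = "male",
                            birth_date = as.Date("2000-06-15"),
                            growth_ref = tiny_growth_ref()) {
  dates <- seq(as.Date(birth_date), by = "year", length.out = age_years + 1)[age_years + 1] +
    day_offsets
  age_m <- age_months_at(birth_date, dates)
  p <- pedhtn:::interp_lms(growth_ref, sex, "height_for_age", age_m)
  visit_rows(person_id = person_id, visit_date = dates, sex = sex,
             birth_date = birth_date, sbp = sbp, dbp = dbp,
             height_cm = p$M, weight_kg = 30)
}
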