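# Synthetic EHR generation: every input the pipeline consumes, with known
# ground truth. Fully deterministic under a fixed seed.

# exact calendar-year addition; a Feb-29 anniversary falls back to Feb-28
add_years <- function(date, n) {
  lt <- as.POSIXlt(as.Date(date))
  feb29 <- lt$mon == 1L & lt$mday == 29L
  lt$year <- lt$year + n
  lt$mday[feb29] <- 28L
  as.Date(lt)
}

#' Simulation configuration
#'
#' Validated parameter set for [gen_cohort()]. Defaults describe a
#' ten-year outpatient panel (2009-2018) of children and adolescents with a
#' low latent hypertension prevalence and modest data-entry defect rates
#' (invalid BP readings are rare in source EHR systems, well under 0.1% of
#' observations; missing heights are far more common).
#'
#' @param n_persons number of persons.
#' @param study_start first day of the study window (ISO date).
#' @param study_years length of the study window in years.
#' @param age_range inclusive age span `c(lo, hi)` in years (1-20).
#' @param years_per_person consecutive years of age each person is
#'   observed.
#' @param htn_prevalence probability a person-year is hypertensive.
#' @param elevated_prevalence probability a person-year is elevated.
#' @param visits_per_year list `(min, lambda)`: occasions per person-year
#'   are `min + Poisson(lambda)`.
#' @param missing_height_rate fraction of visits with height not recorded.
#' @param bp_outlier_rate fraction of visits with an implausible BP value.
#' @param growth_outlier_rate fraction of visits with an implausible
#'   weight entry.
#' @param condition_rates per-body-system probability of a planted chronic
#'   condition (scalar or named vector over [PMCA_BODY_SYSTEMS]).
#' @param margin_mmhg clearance kept between generated readings and the
#'   nearest classification threshold so ground truth is unambiguous; set 0
#'   for boundary testing.
#' @param bp_model `"planted"` (readings follow the planted category) or
#'   `"ambient"` (readings drawn from the normative distribution with no
#'   planted categories).
#' @param seed integer RNG seed; a fixed seed makes the whole generation
#'   chain byte-identical.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_persons = 500,
                       study_start = "2009-01-01",
                       study_years = 10,
                       age_range = c(1, 17),
                       years_per_person = 2,
                       htn_prevalence = 0.01,
                       elevated_prevalence = 0.02,
                       visits_per_year = list(min = 3, lambda = 1),
                       missing_height_rate = 0.05,
                       bp_outlier_rate = 0.001,
                       growth_outlier_rate = 0.001,
                       condition_rates = 0.02,
                       margin_mmhg = 2,
                       bp_model = c("planted", "ambient"),
                       seed = 1) {
  bp_model <- match.arg(bp_model)
  probs <- c(htn_prevalence, elevated_prevalence, missing_height_rate,
             bp_outlier_rate, growth_outlier_rate)
  if (any(probs < 0 | probs > 1)) {
    pedhtn_stop("sim_config: probabilities must be in [0, 1]", "config_error")
  }
  if (htn_prevalence + elevated_prevalence > 1) {
    pedhtn_stop("sim_config: htn_prevalence + elevated_prevalence must be <= 1",
                "config_error")
  }
  if (n_persons <= 0) pedhtn_stop("sim_config: n_persons must be positive", "config_error")
  if (visits_per_year$min < 3 && (htn_prevalence > 0 || elevated_prevalence > 0)) {
    pedhtn_stop("sim_config: visits_per_year$min < 3 cannot express a positive planted prevalence (person-years would be ineligible)",
                "config_error")
  }
  if (age_range[1] < 1 || age_range[2] > 20 || age_range[1] > age_range[2]) {
    pedhtn_stop("sim_config: age_range must lie within [1, 20]", "config_error")
  }
  years_per_person <- min(years_per_person, age_range[2] - age_range[1] + 1)
  if (study_years < years_per_person + 1) {
    pedhtn_stop("sim_config: study window too short for years_per_person", "config_error")
  }
  if (length(condition_rates) == 1 && is.null(names(condition_rates))) {
    condition_rates <- stats::setNames(rep(condition_rates, length(PMCA_BODY_SYSTEMS)),
                                       PMCA_BODY_SYSTEMS)
  }
  structure(list(
    n_persons = as.integer(n_persons), study_start = as.Date(study_start),
    study_years = study_years, age_range = age_range,
    years_per_person = years_per_person,
    htn_prevalence = htn_prevalence, elevated_prevalence = elevated_prevalence,
    visits_per_year = visits_per_year,
    missing_height_rate = missing_height_rate,
    bp_outlier_rate = bp_outlier_rate,
    growth_outlier_rate = growth_outlier_rate,
    condition_rates = condition_rates, margin_mmhg = margin_mmhg,
    bp_model = bp_model, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic LMS growth reference
#'
#' Smooth monotone median curves for height-for-age, weight-for-age and
#' BMI-for-age by sex over ages 12-260 months, with `L = 1` throughout so
#' the z-score has the closed form `(x - M) / (M * S)`. Deterministic given
#' the seed.
#'
#' @param seed integer seed (kept for interface symmetry; the curves are
#'   deterministic).
#' @return growth-reference data.frame (see [read_growth_reference()]).
#' @export
gen_growth_reference <- function(seed = 1) {
  ages <- 12:260
  curve <- function(sex, measure, M, S) {
    data.frame(sex = sex, age_months = ages, measure = measure,
               L = 1, M = M, S = S, stringsAsFactors = FALSE)
  }
  df <- rbind(
    curve("male", "height_for_age", 66 + 0.75 * ages - 0.0012 * ages^2, 0.045),
    curve("female", "height_for_age", 66 + 0.72 * ages - 0.00125 * ages^2, 0.045),
    curve("male", "weight_for_age", 8 + 0.28 * ages - 0.0002 * ages^2, 0.13),
    curve("female", "weight_for_age", 7.8 + 0.27 * ages - 0.0002 * ages^2, 0.13),
    curve("male", "bmi_for_age", 15.5 + 0.012 * (ages - 12), 0.11),
    curve("female", "bmi_for_age", 15.3 + 0.012 * (ages - 12), 0.11)
  )
  validate_growth_reference(df)
}

#' Generate synthetic guideline BP reference tables
#'
#' Percentile values come from a Gaussian normative model linear in age,
#' sex and height z-score: `value = mu(age, sex) + beta * z_height +
#' z_p * sigma`. With `style = "aap_dominant"` the AAP table sits 1 mmHg
#' below the 2004 table, and the model guarantees that the static AAP
#' 130/80 cutoff at ages >= 13 is at or below the 2004 "95th percentile +
#' 5 mmHg" cutoff everywhere on the grid, so the AAP rule set classifies a
#' superset of readings as hypertensive (the direction of reclassification
#' reported for adolescents). The dominance inequality is asserted over the
#' whole grid at generation time.
#'
#' @param seed integer seed (kept for interface symmetry; values are
#'   deterministic).
#' @param style `"aap_dominant"` (default) or `"shared"` (identical
#'   normative values under both guidelines).
#' @return BP reference data.frame (see [read_bp_reference()]).
#' @export
gen_bp_reference <- function(seed = 1, style = c("aap_dominant", "shared")) {
  style <- match.arg(style)
  grid <- expand.grid(
    guideline = GUIDELINES, sex = c("male", "female"), age_years = 1:17,
    height_percentile = HEIGHT_PCT_GRID, metric = c("SBP", "DBP"),
    bp_percentile = c(50, 90, 95),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  male <- grid$sex == "male"
  sbp <- grid$metric == "SBP"
  mu <- ifelse(sbp, 85 + 2.2 * grid$age_years + male,
               50 + 1.3 * grid$age_years + 0.5 * male)
  beta <- ifelse(sbp, 1.5, 1.0)
  sigma <- ifelse(sbp, 10, 8)
  off <- if (style == "aap_dominant") ifelse(grid$guideline == "aap_2017", -1, 0) else 0
  grid$value <- round(mu + off + beta * stats::qnorm(grid$height_percentile / 100) +
                        stats::qnorm(grid$bp_percentile / 100) * sigma, 1)
  tab <- validate_bp_reference(grid)
  if (style == "aap_dominant") {
    p95 <- tab[tab$guideline == "fourth_2004" & tab$bp_percentile == 95 &
                 tab$age_years >= 13, ]
    static <- ifelse(p95$metric == "SBP", 130, 80)
    stopifnot(all(static <= p95$value + 5))
  }
  tab
}

#' Generate a synthetic PMCA code map
#'
#' Deterministic map with at least one ICD-9 and one ICD-10 prefix for each
#' of the 18 body systems, additional progressive-condition prefixes for
#' five systems, and a malignancy-flagged entry. Prefixes are stylized
#' placeholders, not real ICD codes.
#'
#' @param seed integer seed (kept for interface symmetry).
#' @return code-map data.frame (see [read_code_map()]).
#' @export
gen_code_map <- function(seed = 1) {
  n <- length(PMCA_BODY_SYSTEMS)
  base10 <- sprintf("A%02d", seq_len(n) + 9)   # A10..A27
  base9 <- sprintf("%03d", seq_len(n) + 99)    # 100..117
  df <- rbind(
    data.frame(icd_version = 10L, code_prefix = base10,
               body_system = PMCA_BODY_SYSTEMS,
               progressive = FALSE, malignancy = FALSE,
               stringsAsFactors = FALSE),
    data.frame(icd_version = 9L, code_prefix = base9,
               body_system = PMCA_BODY_SYSTEMS,
               progressive = FALSE, malignancy = FALSE,
               stringsAsFactors = FALSE)
  )
  prog_sys <- c("neurological", "renal", "metabolic", "genetic",
                "pulmonary_respiratory")
  df <- rbind(df, data.frame(
    icd_version = 10L,
    code_prefix = sprintf("P%02d", seq_along(prog_sys) + 9),
    body_system = prog_sys, progressive = TRUE, malignancy = FALSE,
    stringsAsFactors = FALSE
  ))
  df$malignancy[df$body_system == "malignancy"] <- TRUE
  validate_code_map(df)
}

# draw n distinct day offsets in 0..364
distinct_days <- function(n) sort(sample.int(365, n) - 1L)

#' Generate a synthetic outpatient cohort with ground truth
#'
#' Builds a longitudinal visit panel: each person carries a latent height
#' and weight track (a persistent z-score against the growth reference) and
#' is observed over consecutive years of age with at least three occasions
#' per year. Under the default `bp_model = "planted"`, each person-year is
#' assigned a true category (hypertensive / elevated / normal) at the
#' configured prevalences and its readings are placed relative to the
#' thresholds resolved per visit under *both* guidelines — hypertensive
#' readings above the larger of the two hypertension cutoffs plus the
#' safety margin, normal readings below the smaller elevated cutoff minus
#' the margin, elevated readings at the midpoint of the cross-guideline
#' band — so the planted label is the correct classification under either
#' guideline. Ground-truth labels are recorded before defect injection
#' (missing heights, implausible BP values, implausible weights);
#' person-years touched by a defect are flagged `defect_free = FALSE`.
#'
#' With `bp_model = "ambient"`, readings are drawn from the normative
#' Gaussian model itself (no planted categories), which produces a natural
#' spread across categories and inter-guideline discordance.
#'
#' Diagnosis histories are planted per person at the configured
#' per-body-system condition rates and emitted as qualifying encounter
#' patterns (two outpatient dates, or one inpatient discharge) in the year
#' before the person's first visit, alongside unmapped background
#' encounters.
#'
#' @param config a [sim_config()].
#' @param growth_ref,bp_tables,code_map optional pre-built references;
#'   generated from `config$seed` when omitted.
#' @return list with `visits`, `encounters`, `ground_truth` (per
#'   person-year: `true_category`, `defect_free`), `ground_truth_pmca`
#'   (per person: planted complexity), `growth_ref`, `bp_tables`,
#'   `code_map`, and the `config`.
#' @export
gen_cohort <- function(config = sim_config(), growth_ref = NULL,
                       bp_tables = NULL, code_map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(growth_ref)) growth_ref <- gen_growth_reference(config$seed)
  if (is.null(bp_tables)) bp_tables <- gen_bp_reference(config$seed)
  if (is.null(code_map)) code_map <- gen_code_map(config$seed)

  np <- config$n_persons
  ny <- config$years_per_person
  persons <- data.frame(
    person_id = sprintf("P%05d", seq_len(np)),
    sex = sample(c("male", "female"), np, replace = TRUE),
    hz = pmax(pmin(stats::rnorm(np), 2.2), -2.2),
    wz = pmax(pmin(stats::rnorm(np), 2.2), -2.2),
    bpz = stats::rnorm(np), # persistent BP level (ambient mode only)
    a0 = sample(seq(config$age_range[1], config$age_range[2] - ny + 1), np,
                replace = TRUE),
    stringsAsFactors = FALSE
  )
  slack <- as.integer(365 * (config$study_years - ny) - 366)
  anchor <- config$study_start + sample.int(max(slack, 1), np, replace = TRUE) - 1L
  persons$birth_date <- add_years(anchor, -persons$a0)

  # person-year table with planted categories
  py <- persons[rep(seq_len(np), each = ny),
                c("person_id", "sex", "birth_date", "hz", "wz", "bpz", "a0")]
  py$age_years <- py$a0 + rep(seq_len(ny) - 1L, times = np)
  if (config$bp_model == "planted") {
    u <- stats::runif(nrow(py))
    py$true_category <- ifelse(u < config$htn_prevalence, "HTN",
                               ifelse(u < config$htn_prevalence + config$elevated_prevalence,
                                      "ELEVATED", "NORMAL"))
  } else {
    py$true_category <- NA_character_
  }
  py$n_visits <- config$visits_per_year$min +
    stats::rpois(nrow(py), config$visits_per_year$lambda)

  # expand to visits
  vi <- py[rep(seq_len(nrow(py)), py$n_visits), ]
  vi$day_offset <- unlist(lapply(py$n_visits, distinct_days), use.names = FALSE)
  vi$visit_date <- add_years(vi$birth_date, vi$age_years) + vi$day_offset
  age_m <- age_months_at(vi$birth_date, vi$visit_date)

  height <- weight <- numeric(nrow(vi))
  for (s in c("male", "female")) {
    idx <- which(vi$sex == s)
    ph <- interp_lms(growth_ref, s, "height_for_age", age_m[idx])
    pw <- interp_lms(growth_ref, s, "weight_for_age", age_m[idx])
    height[idx] <- ph$M * (1 + vi$hz[idx] * ph$S)
    weight[idx] <- pw$M * (1 + vi$wz[idx] * pw$S)
  }
  vi$height_cm <- round(height, 1)
  vi$weight_kg <- round(weight, 1)
  height_pct <- 100 * stats::pnorm(vi$hz)

  # thresholds under both guidelines at each visit
  th <- lapply(GUIDELINES, function(g) {
    resolve_thresholds_batch(
      data.frame(guideline = g, sex = vi$sex, age_years = vi$age_years,
                 height_pct = height_pct, stringsAsFactors = FALSE),
      bp_tables)
  })
  min_elev_s <- pmin(th[[1]]$elevated_sbp, th[[2]]$elevated_sbp)
  max_elev_s <- pmax(th[[1]]$elevated_sbp, th[[2]]$elevated_sbp)
  min_htn_s <- pmin(th[[1]]$htn_sbp, th[[2]]$htn_sbp)
  max_htn_s <- pmax(th[[1]]$htn_sbp, th[[2]]$htn_sbp)
  min_elev_d <- pmin(th[[1]]$elevated_dbp, th[[2]]$elevated_dbp)

  m <- config$margin_mmhg
  nvis <- nrow(vi)
  if (config$bp_model == "planted") {
    sbp <- min_elev_s - m - stats::runif(nvis, 0, 12) # normal default
    htn_i <- vi$true_category == "HTN"
    ele_i <- vi$true_category == "ELEVATED"
    sbp[htn_i] <- max_htn_s[htn_i] + m + stats::runif(sum(htn_i), 0, 8)
    band_lo <- max_elev_s[ele_i]
    band_hi <- min_htn_s[ele_i]
    sbp[ele_i] <- band_lo + (band_hi - band_lo) *
      stats::runif(sum(ele_i), 0.35, 0.65)
    dbp <- min_elev_d - m - stats::runif(nvis, 2, 10)
  } else {
    # person-level BP track plus occasion noise: readings within a child
    # are correlated, as in real panels
    mu_s <- 85 + 2.2 * vi$age_years + (vi$sex == "male") + 1.5 * vi$hz + 9 * vi$bpz
    mu_d <- 50 + 1.3 * vi$age_years + 0.5 * (vi$sex == "male") + vi$hz + 6 * vi$bpz
    sbp <- stats::rnorm(nvis, mu_s, 7)
    dbp <- stats::rnorm(nvis, mu_d, 6)
  }
  vi$sbp <- round(pmax(sbp, 62), 1)
  vi$dbp <- round(pmin(pmax(dbp, 32), vi$sbp - 10), 1)
  vi$setting <- "outpatient"

  # defect injection; ground truth keeps the pre-defect labels
  defect <- rep(FALSE, nvis)
  inject <- function(rate) {
    hit <- stats::runif(nvis) < rate
    defect <<- defect | hit
    hit
  }
  mh <- inject(config$missing_height_rate)
  vi$height_cm[mh] <- NA_real_
  bo <- inject(config$bp_outlier_rate)
  vi$sbp[bo] <- round(stats::runif(sum(bo), 242, 255), 1)
  go <- inject(config$growth_outlier_rate)
  if (any(go)) {
    for (s in c("male", "female")) {
      idx <- which(go & vi$sex == s)
      if (!length(idx)) next
      pw <- interp_lms(growth_ref, s, "weight_for_age", age_m[idx])
      vi$weight_kg[idx] <- round(pw$M * (1 + 7 * pw$S), 1)
    }
  }

  pykey <- paste(vi$person_id, vi$age_years, sep = "|")
  touched <- unique(pykey[defect])
  gt <- py[, c("person_id", "age_years", "sex", "true_category", "n_visits")]
  gt$defect_free <- !paste(gt$person_id, gt$age_years, sep = "|") %in% touched
  rownames(gt) <- NULL

  visits <- vi[order(vi$person_id, vi$visit_date),
               c("person_id", "visit_date", "sex", "birth_date", "sbp", "dbp",
                 "height_cm", "weight_kg", "setting")]
  rownames(visits) <- NULL

  enc <- gen_encounters(persons, visits, code_map, config)

  list(visits = visits, encounters = enc$encounters,
       ground_truth = gt, ground_truth_pmca = enc$ground_truth,
       growth_ref = growth_ref, bp_tables = bp_tables, code_map = code_map,
       config = config)
}

# diagnosis histories: planted conditions emitted as qualifying encounter
# patterns in the year before each person's first visit, plus unmapped
# background encounters for utilization counts.
gen_encounters <- function(persons, visits, code_map, config) {
  first_visit <- tapply(visits$visit_date, visits$person_id, min)
  anchors <- as.Date(as.numeric(first_visit),
                     origin = "1970-01-01")[match(persons$person_id, names(first_visit))]
  rates <- config$condition_rates
  rows <- list(); gtr <- list()
  for (i in seq_len(nrow(persons))) {
    pid <- persons$person_id[i]; anchor <- anchors[i]
    planted <- PMCA_BODY_SYSTEMS[stats::runif(length(PMCA_BODY_SYSTEMS)) <
                                   rates[PMCA_BODY_SYSTEMS]]
    prog <- FALSE; malig <- FALSE
    for (sys in planted) {
      entries <- which(code_map$body_system == sys)
      e <- entries[sample.int(length(entries), 1)]
      prog <- prog || code_map$progressive[e]
      malig <- malig || code_map$malignancy[e]
      code <- paste0(code_map$code_prefix[e], sample.int(9, 1))
      if (stats::runif(1) < 0.3) {
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = pid, date = anchor - sample.int(365, 1),
          setting = "inpatient_discharge",
          icd_version = code_map$icd_version[e], code = code,
          stringsAsFactors = FALSE)
      } else {
        d <- anchor - sort(sample.int(365, 2))
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = pid, date = d, setting = "outpatient",
          icd_version = code_map$icd_version[e], code = code,
          stringsAsFactors = FALSE)
      }
    }
    n_bg <- stats::rpois(1, 2)
    if (n_bg > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = pid, date = anchor - sample.int(365, n_bg, replace = TRUE),
        setting = sample(c("outpatient", "emergency"), n_bg, replace = TRUE,
                         prob = c(0.8, 0.2)),
        icd_version = 10L, code = paste0("Z0", sample.int(9, n_bg, replace = TRUE)),
        stringsAsFactors = FALSE)
    }
    n_sys <- length(unique(planted))
    gtr[[i]] <- data.frame(
      person_id = pid,
      level = if (n_sys >= 2 || prog || malig) "complex_cd"
              else if (n_sys == 1) "non_complex_cd" else "without_cd",
      n_systems = n_sys, progressive = prog, malignancy = malig,
      body_systems = paste(sort(planted), collapse = ","),
      stringsAsFactors = FALSE)
  }
  encounters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(person_id = character(0), date = as.Date(character(0)),
               setting = character(0), icd_version = integer(0),
               code = character(0), stringsAsFactors = FALSE)
  encounters <- encounters[order(encounters$person_id, encounters$date), ]
  rownames(encounters) <- NULL
  list(encounters = encounters, ground_truth = do.call(rbind, gtr))
}

#' Write all simulated artifacts as delimited text
#'
#' Emits `visits.csv`, `encounters.csv`, `ground_truth.csv`,
#' `ground_truth_pmca.csv`, `growth_reference.csv`, `bp_reference.csv`,
#' `code_map.csv` into a directory, in the exact schemas the pipeline
#' readers consume. Byte-identical for a fixed simulation seed.
#'
#' @param sim result of [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE,
                                       quote = FALSE)
  w(sim$visits, "visits.csv")
  w(sim$encounters, "encounters.csv")
  w(sim$ground_truth, "ground_truth.csv")
  w(sim$ground_truth_pmca, "ground_truth_pmca.csv")
  w(sim$growth_ref, "growth_reference.csv")
  w(sim$bp_tables, "bp_reference.csv")
  w(sim$code_map, "code_map.csv")
  invisible(dir)
}
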