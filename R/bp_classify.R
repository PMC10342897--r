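#' Classify a single BP reading against a threshold set
#'
#' Category precedence is hypertension > elevated > normal, with "and/or"
#' logic on the two metrics: hypertensive when SBP or DBP reaches its
#' hypertension cutoff; otherwise elevated when either reaches its elevated
#' cutoff; otherwise normal.
#'
#' @param sbp,dbp readings in mmHg (vectorized).
#' @param thresholds a threshold set from [resolve_thresholds()], or a
#'   data.frame of per-reading threshold rows.
#' @return character vector of `"NORMAL"`, `"ELEVATED"`, `"HTN"`.
#' @export
#' @examples
#' ts <- resolve_thresholds("aap_2017", "male", 15, 50, tables = NULL)
#' classify_visit(c(119, 125, 130), c(79, 75, 70), ts)
classify_visit <- function(sbp, dbp, thresholds) {
  n <- max(length(sbp), length(dbp))
  sbp <- rep_len(sbp, n); dbp <- rep_len(dbp, n)
  es <- rep_len(thresholds$elevated_sbp, n)
  ed <- rep_len(thresholds$elevated_dbp, n)
  hs <- rep_len(thresholds$htn_sbp, n)
  hd <- rep_len(thresholds$htn_dbp, n)
  ifelse(sbp >= hs | dbp >= hd, "HTN",
         ifelse(sbp >= es | dbp >= ed, "ELEVATED", "NORMAL"))
}

# Collapse same-day repeat measurements to one occasion per (person, date).
# mode "first" keeps the first row of the day (input order); "mean" averages
# the numeric measurements.
collapse_same_day <- function(records, mode = c("first", "mean")) {
  mode <- match.arg(mode)
  key <- paste(records$person_id, records$visit_date, sep = "|")
  if (mode == "first") {
    records[!duplicated(key), , drop = FALSE]
  } else {
    first <- records[!duplicated(key), , drop = FALSE]
    fkey <- paste(first$person_id, first$visit_date, sep = "|")
    for (col in intersect(c("sbp", "dbp", "height_cm", "weight_kg"), names(records))) {
      m <- tapply(records[[col]], key, mean, na.rm = TRUE)
      v <- as.numeric(m[fkey])
      first[[col]] <- ifelse(is.nan(v), NA_real_, v)
    }
    first
  }
}

# Shared per-occasion classification work: collapse occasions, derive ages
# and height percentiles, resolve thresholds and classify under one guideline.
classify_occasions <- function(records, guideline, tables, growth_ref,
                               static_rules, same_day) {
  occ <- collapse_same_day(records, same_day)
  occ <- occ[order(occ$person_id, occ$visit_date), , drop = FALSE]
  if (!nrow(occ)) {
    for (col in c("age_years", "height_pct", "sbp_htn", "dbp_htn",
                  "sbp_elev", "dbp_elev", "category")) occ[[col]] <- logical(0)
    return(occ)
  }
  occ$age_years <- age_years_at(occ$birth_date, occ$visit_date)
  age_m <- age_months_at(occ$birth_date, occ$visit_date)
  occ$height_pct <- height_percentile(occ$sex, age_m, occ$height_cm, growth_ref)
  ctx <- data.frame(guideline = guideline, sex = occ$sex,
                    age_years = occ$age_years, height_pct = occ$height_pct,
                    stringsAsFactors = FALSE)
  th <- resolve_thresholds_batch(ctx, tables, static_rules)
  occ$sbp_htn  <- occ$sbp >= th$htn_sbp
  occ$dbp_htn  <- occ$dbp >= th$htn_dbp
  occ$sbp_elev <- occ$sbp >= th$elevated_sbp
  occ$dbp_elev <- occ$dbp >= th$elevated_dbp
  occ$category <- classify_visit(occ$sbp, occ$dbp, th)
  occ
}

person_year_summary <- function(occ, guideline, min_occasions = 3) {
  if (!nrow(occ)) {
    return(data.frame(person_id = character(0), age_years = integer(0),
                      guideline = character(0), n_occasions = integer(0),
                      eligible = logical(0), n_sbp_htn = integer(0),
                      n_dbp_htn = integer(0), n_sbp_elev = integer(0),
                      n_dbp_elev = integer(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(occ$person_id, occ$age_years, drop = TRUE)
  agg <- function(v) as.integer(tapply(v, key, sum))
  first_of <- function(v) tapply(v, key, function(x) x[1])
  out <- data.frame(
    person_id = as.character(first_of(as.character(occ$person_id))),
    age_years = as.integer(first_of(occ$age_years)),
    guideline = guideline,
    n_occasions = as.integer(tapply(key, key, length)),
    n_sbp_htn = agg(occ$sbp_htn), n_dbp_htn = agg(occ$dbp_htn),
    n_sbp_elev = agg(occ$sbp_elev), n_dbp_elev = agg(occ$dbp_elev),
    stringsAsFactors = FALSE
  )
  out$eligible <- out$n_occasions >= min_occasions
  out$category <- ifelse(
    out$eligible & (out$n_sbp_htn >= min_occasions | out$n_dbp_htn >= min_occasions),
    "HTN",
    ifelse(out$eligible & (out$n_sbp_elev >= min_occasions | out$n_dbp_elev >= min_occasions),
           "ELEVATED", "NORMAL"))
  rownames(out) <- NULL
  out[order(out$person_id, out$age_years),
      c("person_id", "age_years", "guideline", "n_occasions", "eligible",
        "n_sbp_htn", "n_dbp_htn", "n_sbp_elev", "n_dbp_elev", "category")]
}

#' Classify one person's visits within one year of age
#'
#' Person-year classification rule: using separate occasions (distinct
#' calendar dates) within one year of age, the person-year is hypertensive
#' when at least `min_occasions` (default 3) SBP readings and/or at least
#' `min_occasions` DBP readings meet the hypertension threshold resolved
#' per visit; elevated by the same logic against the elevated thresholds;
#' otherwise normal. SBP and DBP occasion counts are tallied separately and
#' OR-ed — a mixed pattern of two high-SBP plus two high-DBP occasions does
#' not qualify. A person-year with fewer than `min_occasions` occasions is
#' ineligible (`eligible = FALSE`) and can only be `NORMAL`.
#'
#' @param visits visit data.frame for a single person-year of age.
#' @param guideline `"fourth_2004"` or `"aap_2017"`.
#' @param tables BP reference table.
#' @param growth_ref LMS growth reference.
#' @param static_rules static cutoffs, default [default_static_rules()].
#' @param min_occasions qualifying occasion count (default 3).
#' @param same_day collapse rule for same-day repeats (`"first"`/`"mean"`).
#' @return one-row data.frame with occasion counts and the category.
#' @export
classify_person_year <- function(visits, guideline, tables, growth_ref,
                                 static_rules = default_static_rules(),
                                 min_occasions = 3,
                                 same_day = c("first", "mean")) {
  occ <- classify_occasions(visits, guideline, tables, growth_ref,
                            static_rules, match.arg(same_day))
  if (length(unique(occ$person_id)) > 1 || length(unique(occ$age_years)) > 1) {
    pedhtn_stop("classify_person_year expects visits of one person within one year of age",
                "invalid_parameter")
  }
  person_year_summary(occ, guideline, min_occasions)
}

#' Classify a cleaned cohort under one or both guidelines
#'
#' Produces one row per (person, year of age, guideline) with at least one
#' occasion, carrying occasion counts, the eligibility flag for the
#' minimum-occasion rule, and the person-year category. Deterministic given
#' the input (rows are sorted by person and date before processing).
#'
#' @param records cleaned visit data.frame (post-[run_qc()]).
#' @param tables BP reference table covering both guidelines.
#' @param growth_ref LMS growth reference.
#' @param guidelines character vector of guidelines to classify under.
#' @inheritParams classify_person_year
#' @return data.frame of person-year classifications.
#' @export
classify_cohort <- function(records, tables, growth_ref,
                            guidelines = GUIDELINES,
                            static_rules = default_static_rules(),
                            min_occasions = 3,
                            same_day = c("first", "mean")) {
  same_day <- match.arg(same_day)
  bad_sex <- !records$sex %in% c("male", "female")
  if (any(bad_sex)) {
    pedhtn_stop(paste0("unknown sex code(s) at record row(s) ",
                       paste(utils::head(which(bad_sex), 5), collapse = ", ")),
                "validation_error")
  }
  out <- lapply(guidelines, function(g) {
    occ <- classify_occasions(records, g, tables, growth_ref, static_rules, same_day)
    person_year_summary(occ, g, min_occasions)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a person-year classification table as delimited text
#'
#' @param py person-year data.frame from [classify_cohort()].
#' @param file output path.
#' @export
write_person_years <- function(py, file) {
  utils::write.csv(py, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
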