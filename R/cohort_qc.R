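#' Read an outpatient visit file
#'
#' Delimited text with a header row and columns `person_id`, `visit_date`
#' (ISO-8601), `sex`, `birth_date` (ISO-8601), `sbp`, `dbp`, `height_cm`,
#' `weight_kg`, `setting`. Empty fields in `sbp`, `dbp`, `height_cm`,
#' `weight_kg` are read as missing.
#'
#' @param file path to a delimited text file.
#' @param sep field separator (default comma).
#' @return data.frame of visit records with `Date` date columns.
#' @export
read_visits <- function(file, sep = ",") {
  df <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("person_id", "visit_date", "sex", "birth_date", "sbp", "dbp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pedhtn_stop(paste0("visit file: missing column(s) ",
                       paste(missing_cols, collapse = ", ")), "table_error")
  }
  df$visit_date <- as.Date(df$visit_date)
  df$birth_date <- as.Date(df$birth_date)
  for (col in c("sbp", "dbp", "height_cm", "weight_kg")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df
}

qc_split <- function(records, keep) {
  list(kept = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}

#' QC filter: both SBP and DBP recorded
#'
#' Keeps only visits carrying a complete blood-pressure pair (both systolic
#' and diastolic measured at the same visit).
#'
#' @param records visit data.frame (see [read_visits()]).
#' @return list with `kept` and `excluded` data.frames.
#' @export
require_complete_bp <- function(records) {
  qc_split(records, !is.na(records$sbp) & !is.na(records$dbp))
}

#' QC filter: height measured at the visit
#'
#' Height is the lookup key for the BP percentile tables, so visits without
#' a height measurement cannot be classified. By default the exclusion is
#' per visit; a person drops out entirely only when no visit survives. With
#' `level = "person"` any missing height removes the whole person.
#'
#' @inheritParams require_complete_bp
#' @param level `"visit"` (default) or `"person"`.
#' @return list with `kept` and `excluded` data.frames.
#' @export
require_height <- function(records, level = c("visit", "person")) {
  level <- match.arg(level)
  has_height <- !is.na(records$height_cm)
  if (level == "person") {
    ok_person <- tapply(has_height, records$person_id, all)
    keep <- as.logical(ok_person[as.character(records$person_id)])
    qc_split(records, keep)
  } else {
    qc_split(records, has_height)
  }
}

#' QC filter: implausible growth data
#'
#' Flags incorrect or outlier anthropometrics using LMS z-scores against a
#' growth reference: a visit is excluded when its height-for-age or
#' weight-for-age z-score is below -6 or above +6 standard deviations.
#' The inequalities are strict, so z-scores of exactly +/-6.0 are kept.
#' Weight is checked only when recorded.
#'
#' @inheritParams require_complete_bp
#' @param growth_ref LMS growth reference spanning the records' ages.
#' @param z_limit absolute z bound (default 6).
#' @return list with `kept` and `excluded` data.frames.
#' @export
filter_growth_outliers <- function(records, growth_ref, z_limit = 6) {
  if (!nrow(records)) return(qc_split(records, logical(0)))
  age_m <- age_months_at(records$birth_date, records$visit_date)
  zh <- growth_zscore(growth_ref, records$sex, age_m, records$height_cm, "height_for_age")
  zw <- growth_zscore(growth_ref, records$sex, age_m, records$weight_kg, "weight_for_age")
  lim <- z_limit + 1e-7 # strict bound: a z of exactly +/-z_limit is retained
  out <- (!is.na(zh) & (zh < -lim | zh > lim)) |
    (!is.na(zw) & (zw < -lim | zw > lim))
  qc_split(records, !out)
}

#' QC filter: implausible BP readings
#'
#' Excludes data-entry outliers: SBP above 240 or below 60 mmHg, DBP above
#' 160 or below 30 mmHg. Bounds are exclusive, so readings exactly at a
#' bound (e.g. 240/160) are kept.
#'
#' @inheritParams require_complete_bp
#' @param sbp_min,sbp_max,dbp_min,dbp_max plausibility bounds in mmHg.
#' @return list with `kept` and `excluded` data.frames.
#' @export
filter_bp_outliers <- function(records, sbp_min = 60, sbp_max = 240,
                               dbp_min = 30, dbp_max = 160) {
  keep <- records$sbp >= sbp_min & records$sbp <= sbp_max &
    records$dbp >= dbp_min & records$dbp <= dbp_max
  keep[is.na(keep)] <- FALSE
  qc_split(records, keep)
}

#' QC filter: minimum number of separate measurement occasions
#'
#' A person is kept only with at least `k` visits on distinct dates, any
#' two retained occasions at least `min_gap` days apart (with the default
#' `min_gap = 1` this is simply `k` distinct calendar dates). Persons with
#' fewer occasions over the whole study period are removed along with all
#' their records.
#'
#' @inheritParams require_complete_bp
#' @param k minimum occasion count (default 3).
#' @param min_gap minimum spacing in days between occasions (default 1).
#' @return list with `kept` and `excluded` data.frames.
#' @export
min_occasions_filter <- function(records, k = 3, min_gap = 1) {
  if (!nrow(records)) return(qc_split(records, logical(0)))
  n_occ <- tapply(records$visit_date, records$person_id, function(d) {
    d <- sort(unique(d))
    if (min_gap <= 1) return(length(d))
    # greedy thinning: occasions spaced >= min_gap days
    count <- 1L; last <- d[1]
    for (i in seq_along(d)[-1]) {
      if (as.numeric(d[i] - last) >= min_gap) { count <- count + 1L; last <- d[i] }
    }
    count
  })
  ok <- names(n_occ)[n_occ >= k]
  qc_split(records, as.character(records$person_id) %in% ok)
}

#' Run the full QC cascade with attrition accounting
#'
#' Applies the cohort-construction filters in a fixed order — complete BP
#' pair, height present, growth-outlier z-screen, BP plausibility bounds,
#' minimum separate occasions — and records how many records and persons
#' each stage removed.
#'
#' @inheritParams require_complete_bp
#' @param growth_ref LMS growth reference for the z-screen.
#' @param config optional list overriding defaults: `z_limit`, `sbp_min`,
#'   `sbp_max`, `dbp_min`, `dbp_max`, `min_occasions`, `min_gap_days`,
#'   `height_level` (`"visit"`/`"person"`).
#' @return list with `records` (cleaned data.frame) and `attrition`
#'   (data.frame: `stage`, `records_in`, `records_excluded`, `persons_in`,
#'   `persons_excluded`).
#' @export
run_qc <- function(records, growth_ref, config = list()) {
  cfg <- utils::modifyList(list(
    z_limit = 6, sbp_min = 60, sbp_max = 240, dbp_min = 30, dbp_max = 160,
    min_occasions = 3, min_gap_days = 1, height_level = "visit"
  ), config)

  stages <- list(
    complete_bp     = function(r) require_complete_bp(r),
    height_present  = function(r) require_height(r, level = cfg$height_level),
    growth_outliers = function(r) filter_growth_outliers(r, growth_ref, cfg$z_limit),
    bp_outliers     = function(r) filter_bp_outliers(r, cfg$sbp_min, cfg$sbp_max,
                                                     cfg$dbp_min, cfg$dbp_max),
    min_occasions   = function(r) min_occasions_filter(r, cfg$min_occasions,
                                                       cfg$min_gap_days)
  )
  att <- data.frame(stage = character(0), records_in = integer(0),
                    records_excluded = integer(0), persons_in = integer(0),
                    persons_excluded = integer(0), stringsAsFactors = FALSE)
  cur <- records
  for (nm in names(stages)) {
    res <- stages[[nm]](cur)
    att <- rbind(att, data.frame(
      stage = nm,
      records_in = nrow(cur),
      records_excluded = nrow(res$excluded),
      persons_in = length(unique(cur$person_id)),
      persons_excluded = length(unique(cur$person_id)) -
        length(unique(res$kept$person_id)),
      stringsAsFactors = FALSE
    ))
    cur <- res$kept
  }
  list(records = cur, attrition = att)
}

#' Write an attrition report as delimited text
#'
#' @param attrition attrition data.frame from [run_qc()].
#' @param file output path.
#' @export
write_attrition <- function(attrition, file) {
  utils::write.csv(attrition, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
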