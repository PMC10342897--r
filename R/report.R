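#' Default age strata for surveillance reports
#'
#' The reporting strata: 1-7, 8-12, 13-17 and 18-20 years. Groups are not
#' mutually exclusive in general and can be overridden in the report
#' functions.
#' @return named list of `c(lo, hi)` vectors.
#' @export
default_age_groups <- function() {
  list("1-7" = c(1, 7), "8-12" = c(8, 12), "13-17" = c(13, 17),
       "18-20" = c(18, 20))
}

#' Guideline-comparison summary by age group
#'
#' One row per age group: person-year participants, hypertension cases and
#' rate per 1000 persons under each guideline, Cohen's kappa with its 95%
#' CI and interpretation band, and percent agreement. Kappa is computed
#' only for groups where both guidelines are present in the table.
#'
#' @param py person-year table from [classify_cohort()].
#' @param age_groups named list of `c(lo, hi)` age spans (default
#'   [default_age_groups()] without the adult stratum when absent from the
#'   data).
#' @param denominator `"any_obp"` or `"eligible_only"` (see
#'   [participants_at_risk()]).
#' @return data.frame summary.
#' @export
report_rates_agreement <- function(py, age_groups = default_age_groups(),
                                   denominator = c("any_obp", "eligible_only")) {
  denominator <- match.arg(denominator)
  rows <- lapply(names(age_groups), function(nm) {
    grp <- age_groups[[nm]]
    if (!any(py$age_years >= grp[1] & py$age_years <= grp[2])) return(NULL)
    r04 <- rate_by_age_group(py, grp, "fourth_2004", denominator)
    r17 <- rate_by_age_group(py, grp, "aap_2017", denominator)
    ag <- tryCatch(guideline_agreement(py, grp, denominator),
                   pedhtn_error = function(e) NULL)
    data.frame(
      age_group = nm, participants = r04$participants,
      cases_fourth_2004 = r04$cases, rate_fourth_2004 = r04$rate_per_1000,
      cases_aap_2017 = r17$cases, rate_aap_2017 = r17$rate_per_1000,
      kappa = if (is.null(ag)) NA_real_ else round_half_up(ag$kappa, 2),
      kappa_ci_low = if (is.null(ag)) NA_real_ else round_half_up(ag$ci_low, 2),
      kappa_ci_high = if (is.null(ag)) NA_real_ else round_half_up(ag$ci_high, 2),
      kappa_band = if (is.null(ag)) NA_character_ else ag$band,
      pct_agreement = if (is.null(ag)) NA_real_ else round_half_up(ag$pct_agreement, 2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annual hypertension-rate series
#'
#' Annual rates per 1000 persons for each guideline over the calendar span
#' of the records, for trend plotting.
#'
#' @param py person-year table from [classify_cohort()].
#' @param records the cleaned visit records the table was built from.
#' @param guidelines guidelines to include.
#' @return data.frame: `year`, `guideline`, `cases`, `participants`,
#'   `rate_per_1000`.
#' @export
report_annual_series <- function(py, records, guidelines = GUIDELINES) {
  years <- sort(unique(as.integer(format(records$visit_date, "%Y"))))
  rows <- lapply(guidelines, function(g) {
    do.call(rbind, lapply(years, function(y) {
      r <- annual_rate(py, records, y, g)
      data.frame(year = y, guideline = g, cases = r$cases,
                 participants = r$participants,
                 rate_per_1000 = r$rate_per_1000, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the annual hypertension-rate series
#'
#' Base-graphics line plot of [report_annual_series()] output, one line per
#' guideline.
#'
#' @param series data.frame from [report_annual_series()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_annual_series <- function(series, ...) {
  wide <- tapply(series$rate_per_1000, list(series$year, series$guideline), identity)
  graphics::matplot(as.integer(rownames(wide)), wide, type = "b", pch = 16,
                    lty = 1, xlab = "calendar year",
                    ylab = "hypertension rate / 1000 persons", ...)
  graphics::legend("topleft", legend = colnames(wide), col = seq_len(ncol(wide)),
                   lty = 1, pch = 16, bty = "n")
  invisible(wide)
}

#' Run the full surveillance pipeline on raw inputs
#'
#' Orchestrates QC, dual-guideline person-year classification, rate and
#' agreement reporting, the annual series, and (when encounters and a code
#' map are supplied) medical-complexity classification anchored at each
#' person's first retained visit.
#'
#' @param visits raw visit data.frame (see [read_visits()]).
#' @param growth_ref LMS growth reference.
#' @param bp_tables guideline BP reference table.
#' @param encounters optional encounter data.frame for PMCA.
#' @param code_map optional PMCA code map.
#' @param qc_config list of QC overrides (see [run_qc()]).
#' @param denominator rate/agreement denominator mode.
#' @param age_groups named list of age strata.
#' @return list: `qc` (records + attrition), `person_years`, `report`
#'   (rates/agreement by age group), `annual` (annual series), `pmca`
#'   (complexity table or `NULL`).
#' @export
run_pipeline <- function(visits, growth_ref, bp_tables, encounters = NULL,
                         code_map = NULL, qc_config = list(),
                         denominator = c("any_obp", "eligible_only"),
                         age_groups = default_age_groups()) {
  denominator <- match.arg(denominator)
  qc <- run_qc(visits, growth_ref, qc_config)
  py <- classify_cohort(qc$records, bp_tables, growth_ref)
  rep_tab <- report_rates_agreement(py, age_groups, denominator)
  annual <- report_annual_series(py, qc$records)
  pmca <- NULL
  if (!is.null(encounters) && !is.null(code_map)) {
    first <- tapply(qc$records$visit_date, qc$records$person_id, min)
    idx <- data.frame(person_id = names(first),
                      index_date = as.Date(as.numeric(first), origin = "1970-01-01"),
                      stringsAsFactors = FALSE)
    pmca <- classify_pmca(encounters, code_map, idx)
  }
  list(qc = qc, person_years = py, report = rep_tab, annual = annual,
       pmca = pmca)
}
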