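#' Event rate per 1000 persons
#'
#' Cases divided by participants at risk, scaled to 1000 and rounded
#' half-up to two decimals for presentation.
#'
#' @param cases number of cases (0 <= cases <= participants).
#' @param participants number of participants at risk (> 0).
#' @return rate per 1000 persons (2 decimal places).
#' @export
#' @examples
#' event_rate(1300, 218368) # 5.95
event_rate <- function(cases, participants) {
  if (any(participants <= 0)) {
    pedhtn_stop("event_rate: participants must be positive", "undefined_rate")
  }
  if (any(cases < 0 | cases > participants)) {
    pedhtn_stop("event_rate: cases must be in [0, participants]", "invalid_parameter")
  }
  round_half_up(1000 * cases / participants, 2)
}

#' Participants at risk within an age group
#'
#' Counts person-year units: each (person, year of age) with at least one
#' outpatient BP occasion contributes once for every year of age falling in
#' the group. Age groups need not be mutually exclusive.
#'
#' @param py person-year table from [classify_cohort()].
#' @param age_group length-2 numeric `c(lo, hi)`, inclusive.
#' @param denominator `"any_obp"` (default; every person-year with >= 1
#'   occasion) or `"eligible_only"` (person-years meeting the
#'   minimum-occasion rule).
#' @return integer count of person-year units.
#' @export
participants_at_risk <- function(py, age_group,
                                 denominator = c("any_obp", "eligible_only")) {
  denominator <- match.arg(denominator)
  sub <- py[py$age_years >= age_group[1] & py$age_years <= age_group[2], ]
  if (denominator == "eligible_only") sub <- sub[sub$eligible, ]
  nrow(unique(sub[, c("person_id", "age_years")]))
}

#' Hypertension rate in an age group under one guideline
#'
#' @inheritParams participants_at_risk
#' @param guideline guideline to count cases under.
#' @return one-row data.frame: `stratum`, `guideline`, `cases`,
#'   `participants`, `rate_per_1000`.
#' @export
rate_by_age_group <- function(py, age_group, guideline,
                              denominator = c("any_obp", "eligible_only")) {
  denominator <- match.arg(denominator)
  participants <- participants_at_risk(py, age_group, denominator)
  sub <- py[py$guideline == guideline &
              py$age_years >= age_group[1] & py$age_years <= age_group[2], ]
  if (denominator == "eligible_only") sub <- sub[sub$eligible, ]
  cases <- sum(sub$category == "HTN")
  data.frame(stratum = paste0(age_group[1], "-", age_group[2]),
             guideline = guideline, cases = cases, participants = participants,
             rate_per_1000 = event_rate(cases, participants),
             stringsAsFactors = FALSE)
}

#' Annual hypertension rate in a calendar year
#'
#' Denominator: distinct persons with at least one outpatient BP visit in
#' the calendar year. Numerator: distinct persons with a hypertensive
#' person-year that has at least one occasion in that year.
#'
#' @param py person-year table from [classify_cohort()].
#' @param records the cleaned visit records the table was built from.
#' @param calendar_year year to evaluate.
#' @param guideline guideline to count cases under.
#' @return one-row data.frame: `stratum` (the year), `guideline`, `cases`,
#'   `participants`, `rate_per_1000`.
#' @export
annual_rate <- function(py, records, calendar_year, guideline) {
  yr <- as.integer(format(records$visit_date, "%Y"))
  in_year <- records[yr == calendar_year, ]
  participants <- length(unique(in_year$person_id))
  if (participants == 0) {
    pedhtn_stop(paste0("no outpatient BP visits in calendar year ", calendar_year),
                "undefined_rate")
  }
  htn <- py[py$guideline == guideline & py$category == "HTN", ]
  in_year$age_years <- age_years_at(in_year$birth_date, in_year$visit_date)
  hit <- merge(unique(in_year[, c("person_id", "age_years")]),
               htn[, c("person_id", "age_years")],
               by = c("person_id", "age_years"))
  cases <- length(unique(hit$person_id))
  data.frame(stratum = as.character(calendar_year), guideline = guideline,
             cases = cases, participants = participants,
             rate_per_1000 = event_rate(cases, participants),
             stringsAsFactors = FALSE)
}

#' Cohen's kappa for a 2x2 concordance table
#'
#' Chance-corrected agreement between two classifications of the same
#' units. `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = (n11 + n00)/N` and chance agreement `pe` from the marginal
#' products. The standard error uses the large-sample
#' Fleiss-Cohen-Everitt asymptotic variance and the 95% CI is
#' `kappa +/- 1.96 SE`, truncated to `[-1, 1]`.
#'
#' @param n11 units classified case by both raters.
#' @param n10 case by rater 1 only.
#' @param n01 case by rater 2 only.
#' @param n00 non-case by both.
#' @return object of class `agreement_result`: a list with the cell counts,
#'   `kappa`, `se`, `ci_low`, `ci_high`, `pct_agreement` and the
#'   interpretation `band` (see [kappa_band()]).
#' @export
#' @examples
#' cohens_kappa(40, 5, 5, 50) # kappa ~ 0.798
cohens_kappa <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  if (N <= 0) pedhtn_stop("cohens_kappa: empty table", "invalid_parameter")
  p <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE) / N
  pi_ <- rowSums(p); p_j <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pi_ * p_j)
  pct <- 100 * po
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    pedhtn_stop(paste0("cohens_kappa: degenerate margins (pe = 1); percent agreement = ",
                       round_half_up(pct, 2)), "kappa_undefined")
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  a <- sum(diag(p) * (1 - (pi_ + p_j) * (1 - kappa))^2)
  off <- which(row(p) != col(p))
  b <- (1 - kappa)^2 * sum(p[off] * (p_j[row(p)[off]] + pi_[col(p)[off]])^2)
  c_ <- (kappa - pe * (1 - kappa))^2
  var_k <- (a + b - c_) / (N * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  structure(list(
    n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = N,
    kappa = kappa, se = se,
    ci_low = max(-1, kappa - 1.96 * se),
    ci_high = min(1, kappa + 1.96 * se),
    pct_agreement = pct,
    band = kappa_band(kappa)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("Cohen's kappa agreement (2x2)\n")
  cat(sprintf("  cells: n11=%d n10=%d n01=%d n00=%d (N=%d)\n",
              x$n11, x$n10, x$n01, x$n00, x$n))
  cat(sprintf("  kappa = %.4f (95%% CI %.4f-%.4f), SE %.4f [%s]\n",
              x$kappa, x$ci_low, x$ci_high, x$se, x$band))
  cat(sprintf("  percent agreement = %.2f%%\n", x$pct_agreement))
  invisible(x)
}

#' Interpretation band for a kappa estimate
#'
#' Bands: kappa <= 0.20 no agreement; 0.21-0.40 fair; 0.41-0.60 moderate;
#' 0.61-0.80 substantial; 0.81-1.00 almost perfect. The estimate is rounded
#' half-up to two decimals before banding so values in (0.20, 0.21) fall on
#' a printed boundary.
#'
#' @param kappa kappa estimate in `[-1, 1]`.
#' @return one of `"none"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost_perfect"`.
#' @export
kappa_band <- function(kappa) {
  k <- round_half_up(kappa, 2)
  ifelse(k <= 0.20, "none",
         ifelse(k <= 0.40, "fair",
                ifelse(k <= 0.60, "moderate",
                       ifelse(k <= 0.80, "substantial", "almost_perfect"))))
}

#' Inter-guideline agreement on hypertension within an age group
#'
#' Dichotomizes each person-year unit as hypertensive versus not under each
#' guideline, aligns the units, builds the 2x2 concordance table (rater 1 =
#' 2004 Fourth Report, rater 2 = 2017 AAP) and delegates to
#' [cohens_kappa()].
#'
#' @inheritParams participants_at_risk
#' @param guidelines the two guidelines to compare (order = rater order).
#' @return an `agreement_result`.
#' @export
guideline_agreement <- function(py, age_group,
                                denominator = c("any_obp", "eligible_only"),
                                guidelines = GUIDELINES) {
  denominator <- match.arg(denominator)
  sub <- py[py$age_years >= age_group[1] & py$age_years <= age_group[2], ]
  if (denominator == "eligible_only") sub <- sub[sub$eligible, ]
  if (!nrow(sub)) {
    pedhtn_stop("guideline_agreement: no person-years in age group", "invalid_parameter")
  }
  a <- sub[sub$guideline == guidelines[1], ]
  b <- sub[sub$guideline == guidelines[2], ]
  ka <- paste(a$person_id, a$age_years, sep = "|")
  kb <- paste(b$person_id, b$age_years, sep = "|")
  if (length(ka) != length(kb) || !setequal(ka, kb)) {
    pedhtn_stop("guideline_agreement: person-year units differ between guidelines",
                "alignment_error")
  }
  b <- b[match(ka, kb), ]
  ca <- a$category == "HTN"
  cb <- b$category == "HTN"
  cohens_kappa(sum(ca & cb), sum(ca & !cb), sum(!ca & cb), sum(!ca & !cb))
}

#' BMI category from sex- and age-specific percentiles
#'
#' BMI (kg/m^2) is converted to a percentile with the LMS bmi-for-age
#' reference, then categorized: underweight below the 5th percentile,
#' overweight at the 85th up to (not including) the 95th, obesity at or
#' above the 95th, normal otherwise.
#'
#' @param weight_kg,height_cm anthropometrics (vectorized).
#' @param sex `"male"`/`"female"` (vectorized).
#' @param age_months age in completed months (vectorized).
#' @param bmi_ref LMS reference containing a `bmi_for_age` series.
#' @return character vector of `"underweight"`, `"normal"`, `"overweight"`,
#'   `"obesity"`.
#' @export
bmi_category <- function(weight_kg, height_cm, sex, age_months, bmi_ref) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_cm <= 0, na.rm = TRUE)) {
    pedhtn_stop("bmi_category: weight and height must be positive", "invalid_parameter")
  }
  bmi <- weight_kg / (height_cm / 100)^2
  z <- growth_zscore(bmi_ref, sex, age_months, bmi, "bmi_for_age")
  pct <- 100 * stats::pnorm(z)
  ifelse(pct < 5, "underweight",
         ifelse(pct < 85, "normal",
                ifelse(pct < 95, "overweight", "obesity")))
}

#' Logistic association analysis (adjusted odds ratios)
#'
#' Ordinary maximum-likelihood logistic regression of a binary outcome
#' (hypertensive person-year versus elevated/normal pooled) on patient
#' covariates, fitted separately within an age group when `age_group` is
#' given. Reports adjusted odds ratios with Wald 95% confidence intervals.
#'
#' @param data data.frame with one row per analysis unit.
#' @param outcome name of a binary (0/1 or logical) outcome column.
#' @param covariates character vector of covariate column names.
#' @param age_group optional `c(lo, hi)` filter on an `age_years` column.
#' @return data.frame: `term`, `aOR`, `ci_low`, `ci_high`, `p_value`.
#' @export
logistic_or <- function(data, outcome, covariates, age_group = NULL) {
  if (!is.null(age_group)) {
    data <- data[data$age_years >= age_group[1] & data$age_years <= age_group[2], ]
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    pedhtn_stop("logistic_or: outcome is constant (need >= 1 event and >= 1 non-event)",
                "invalid_parameter")
  }
  data$.outcome <- y
  f <- stats::as.formula(paste(".outcome ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = data, family = stats::binomial(),
                                     control = list(epsilon = 1e-8, maxit = 100)))
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  big <- se > 50 | abs(est) > 15
  if (any(big[-1])) {
    pedhtn_stop(paste0("logistic_or: complete or quasi-complete separation suspected for ",
                       paste(rownames(sm)[-1][big[-1]], collapse = ", ")),
                "separation_error")
  }
  keep <- rownames(sm) != "(Intercept)"
  data.frame(
    term = rownames(sm)[keep],
    aOR = exp(est[keep]),
    ci_low = exp(est[keep] - 1.96 * se[keep]),
    ci_high = exp(est[keep] + 1.96 * se[keep]),
    p_value = sm[keep, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
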