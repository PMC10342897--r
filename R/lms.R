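#' LMS z-score transform
#'
#' Converts a measurement to a standard-deviation score under the LMS
#' (lambda-mu-sigma) growth-reference parameterization: for `L != 0`,
#' `z = ((x/M)^L - 1) / (L * S)`; in the limit `L = 0`, `z = log(x/M) / S`.
#' The transform is continuous in `L` at 0 and strictly increasing in `x`.
#'
#' @param x measurement (same units as `M`; must be positive).
#' @param L power of the Box-Cox transform (dimensionless).
#' @param M reference median (positive).
#' @param S reference coefficient of variation (positive).
#' @return numeric z-score(s). Vectorized over all arguments.
#' @export
#' @examples
#' lms_zscore(16.5, L = 1, M = 15, S = 0.1) # (x - M)/(M*S) = 1
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(x) | x <= 0)) {
    pedhtn_stop("lms_zscore: 'x' must be positive and finite", "invalid_parameter")
  }
  if (any(!is.finite(M) | M <= 0) || any(!is.finite(S) | S <= 0)) {
    pedhtn_stop("lms_zscore: 'M' and 'S' must be positive and finite", "invalid_parameter")
  }
  z <- numeric(n)
  zero <- L == 0
  z[zero] <- log(x[zero] / M[zero]) / S[zero]
  z[!zero] <- ((x[!zero] / M[!zero])^L[!zero] - 1) / (L[!zero] * S[!zero])
  z
}

#' Percentile from a z-score
#'
#' Standard-normal cumulative probability expressed as a percentile in
#' (0, 100). `percentile_from_z(0)` is exactly 50.
#'
#' @param z finite z-score(s).
#' @return percentile(s) in (0, 100).
#' @export
percentile_from_z <- function(z) {
  if (any(!is.finite(z))) pedhtn_stop("percentile_from_z: 'z' must be finite", "invalid_parameter")
  100 * stats::pnorm(z)
}

#' Read and validate an LMS growth reference
#'
#' The growth-reference file is delimited text with a header row and columns
#' `sex` (`male`/`female`), `age_months` (integer, >= 12), `measure`
#' (`height_for_age`, `weight_for_age`, `bmi_for_age`), `L`, `M`, `S`.
#' Within each (sex, measure) series `age_months` must be strictly
#' increasing, and `M > 0`, `S > 0` everywhere; violations are reported with
#' row numbers.
#'
#' @param file path to a delimited text file.
#' @param sep field separator (default comma).
#' @return validated `data.frame` of LMS rows.
#' @seealso [validate_growth_reference()], [gen_growth_reference()]
#' @export
read_growth_reference <- function(file, sep = ",") {
  df <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE)
  validate_growth_reference(df)
}

#' @rdname read_growth_reference
#' @param df a data.frame with the growth-reference columns.
#' @export
validate_growth_reference <- function(df) {
  need <- c("sex", "age_months", "measure", "L", "M", "S")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pedhtn_stop(paste0("growth reference: missing column(s) ",
                       paste(missing_cols, collapse = ", ")), "table_error")
  }
  bad <- which(!is.finite(df$M) | df$M <= 0 | !is.finite(df$S) | df$S <= 0)
  if (length(bad)) {
    pedhtn_stop(paste0("growth reference: non-positive M or S at row(s) ",
                       paste(utils::head(bad, 5), collapse = ", ")), "table_error")
  }
  for (key in split(seq_len(nrow(df)), list(df$sex, df$measure), drop = TRUE)) {
    ages <- df$age_months[key]
    if (any(diff(ages) <= 0)) {
      r <- key[which(diff(ages) <= 0)[1] + 1]
      pedhtn_stop(paste0("growth reference: age_months not strictly increasing at row ", r),
                  "table_error")
    }
  }
  df
}

# Interpolate L, M, S at arbitrary ages for one (sex, measure) series.
# Linear in each parameter between bracketing month rows; errors outside span.
interp_lms <- function(growth_ref, sex, measure, age_months) {
  sub <- growth_ref[growth_ref$sex == sex & growth_ref$measure == measure, ]
  if (!nrow(sub)) {
    pedhtn_stop(paste0("growth reference has no rows for sex=", sex,
                       ", measure=", measure), "out_of_range")
  }
  rng <- range(sub$age_months)
  if (any(age_months < rng[1] | age_months > rng[2])) {
    pedhtn_stop(paste0("age ", age_months[which(age_months < rng[1] | age_months > rng[2])[1]],
                       " months outside growth reference span [", rng[1], ", ", rng[2],
                       "] for ", sex, " ", measure), "out_of_range")
  }
  list(
    L = stats::approx(sub$age_months, sub$L, xout = age_months)$y,
    M = stats::approx(sub$age_months, sub$M, xout = age_months)$y,
    S = stats::approx(sub$age_months, sub$S, xout = age_months)$y
  )
}

# Vectorized z-score for one measure across mixed sexes/ages.
growth_zscore <- function(growth_ref, sex, age_months, x, measure) {
  n <- max(length(sex), length(age_months), length(x))
  sex <- rep_len(as.character(sex), n)
  age_months <- rep_len(age_months, n)
  x <- rep_len(x, n)
  z <- rep(NA_real_, n)
  ok <- !is.na(x)
  for (s in unique(sex[ok])) {
    idx <- which(ok & sex == s)
    p <- interp_lms(growth_ref, s, measure, age_months[idx])
    z[idx] <- lms_zscore(x[idx], p$L, p$M, p$S)
  }
  z
}

#' Height percentile from an LMS growth reference
#'
#' Interpolates the L, M, S parameters linearly between the bracketing
#' month rows of the height-for-age series, converts the height to a
#' z-score, and maps it to a percentile via the standard-normal CDF. This
#' percentile is the lookup key into the guideline BP reference tables.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param age_months age in completed months (vectorized).
#' @param height_cm standing height in cm (vectorized).
#' @param growth_ref growth reference as returned by
#'   [read_growth_reference()] or [gen_growth_reference()].
#' @return percentile(s) in (0, 100).
#' @export
height_percentile <- function(sex, age_months, height_cm, growth_ref) {
  percentile_from_z(growth_zscore(growth_ref, sex, age_months, height_cm,
                                  "height_for_age"))
}
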