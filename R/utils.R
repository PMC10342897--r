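#' Round half away from zero
#'
#' Presentation rounding used for rates and kappa: ties go up (5.955 -> 5.96),
#' unlike [base::round()]'s round-half-even. A small guard absorbs binary
#' representation error in ratios of integers.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(1000 * 1300 / 218368, 2) # 5.95
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Completed years / months of age at a date
#'
#' Age attained: the number of whole years (or months) elapsed since birth,
#' i.e. age k from the k-th birthday up to (not including) the (k+1)-th.
#'
#' @param birth_date,at_date `Date` vectors (recycled to common length).
#' @return integer vector of completed years (months).
#' @export
age_years_at <- function(birth_date, at_date) {
  b <- as.POSIXlt(as.Date(birth_date))
  a <- as.POSIXlt(as.Date(at_date))
  yrs <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - before_birthday)
}

#' @rdname age_years_at
#' @export
age_months_at <- function(birth_date, at_date) {
  b <- as.POSIXlt(as.Date(birth_date))
  a <- as.POSIXlt(as.Date(at_date))
  mon <- 12L * (a$year - b$year) + (a$mon - b$mon)
  as.integer(mon - (a$mday < b$mday))
}

# stop() with a class so callers can distinguish validation failures
pedhtn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pedhtn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
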