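#' Read and validate a guideline BP reference table
#'
#' Normative blood-pressure values indexed by guideline, sex, age, height
#' percentile, metric and BP percentile. The file is delimited text with a
#' header row and columns `guideline` (`fourth_2004`/`aap_2017`), `sex`
#' (`male`/`female`), `age_years` (integer 1-17), `height_percentile` (one
#' of 5, 10, 25, 50, 75, 90, 95), `metric` (`SBP`/`DBP`), `bp_percentile`
#' (one of 50, 90, 95) and `value` (mmHg).
#'
#' Two invariants are enforced on load and reported with row numbers when
#' violated: at fixed other keys, `value` must be strictly increasing in
#' `bp_percentile` and non-decreasing in `height_percentile`.
#'
#' The published guideline tables are not bundled; any file conforming to
#' this schema can be supplied, and [gen_bp_reference()] produces synthetic
#' tables with the same structure for testing.
#'
#' @param file path to a delimited text file.
#' @param sep field separator (default comma).
#' @return validated `data.frame` of reference rows.
#' @export
read_bp_reference <- function(file, sep = ",") {
  df <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE)
  validate_bp_reference(df)
}

#' @rdname read_bp_reference
#' @param df a data.frame with the reference-table columns.
#' @export
validate_bp_reference <- function(df) {
  need <- c("guideline", "sex", "age_years", "height_percentile",
            "metric", "bp_percentile", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pedhtn_stop(paste0("BP reference: missing column(s) ",
                       paste(missing_cols, collapse = ", ")), "table_error")
  }
  if (any(!is.finite(df$value))) {
    pedhtn_stop(paste0("BP reference: non-finite value at row ",
                       which(!is.finite(df$value))[1]), "table_error")
  }
  # strictly increasing in bp_percentile at fixed other keys
  key1 <- interaction(df$guideline, df$sex, df$age_years,
                      df$height_percentile, df$metric, drop = TRUE)
  for (idx in split(seq_len(nrow(df)), key1)) {
    o <- idx[order(df$bp_percentile[idx])]
    if (any(diff(df$value[o]) <= 0)) {
      r <- o[which(diff(df$value[o]) <= 0)[1] + 1]
      pedhtn_stop(paste0("BP reference: value not strictly increasing in bp_percentile at row ", r),
                  "table_error")
    }
  }
  # non-decreasing in height_percentile at fixed other keys
  key2 <- interaction(df$guideline, df$sex, df$age_years,
                      df$metric, df$bp_percentile, drop = TRUE)
  for (idx in split(seq_len(nrow(df)), key2)) {
    o <- idx[order(df$height_percentile[idx])]
    if (any(diff(df$value[o]) < 0)) {
      r <- o[which(diff(df$value[o]) < 0)[1] + 1]
      pedhtn_stop(paste0("BP reference: value decreasing in height_percentile at row ", r),
                  "table_error")
    }
  }
  df
}

#' Look up a normative BP value with height-percentile interpolation
#'
#' Returns the guideline table value at the requested BP percentile,
#' interpolating linearly across the height-percentile grid columns. A
#' height percentile outside the grid (below 5 or above 95) clamps to the
#' boundary column, matching common clinical-calculator practice. At a grid
#' column the raw cell value is returned exactly.
#'
#' @param table reference table (see [read_bp_reference()]).
#' @param guideline `"fourth_2004"` or `"aap_2017"`.
#' @param sex `"male"` or `"female"`.
#' @param age_years integer age 1-17.
#' @param height_pct height percentile of the child (any value in (0, 100)).
#' @param metric `"SBP"` or `"DBP"`.
#' @param bp_pct BP percentile to look up (50, 90 or 95).
#' @return normative BP in mmHg.
#' @export
bp_percentile_value <- function(table, guideline, sex, age_years, height_pct,
                                metric, bp_pct) {
  sub <- table[table$guideline == guideline & table$sex == sex &
                 table$age_years == age_years & table$metric == metric &
                 table$bp_percentile == bp_pct, ]
  if (!nrow(sub)) {
    pedhtn_stop(paste0("BP reference table incomplete: no rows for guideline=",
                       guideline, ", sex=", sex, ", age_years=", age_years,
                       ", metric=", metric, ", bp_percentile=", bp_pct),
                "table_incomplete")
  }
  sub <- sub[order(sub$height_percentile), ]
  if (nrow(sub) == 1) return(sub$value)
  stats::approx(sub$height_percentile, sub$value, xout = height_pct, rule = 2)$y
}

#' Default static classification rules
#'
#' Fixed (non-percentile) cutoffs used by the guideline engine: the 2017
#' AAP static thresholds for adolescents >= 13 years (elevated at 120/80,
#' hypertension at 130/80 mmHg), and the adult rule applied by both
#' guidelines at ages 18-20 (hypertension at SBP >= 140 and/or DBP >= 90,
#' with the 120/80 elevated floor retained).
#'
#' @return data.frame with columns `guideline`, `age_min_years`,
#'   `age_max_years`, `elevated_sbp`, `elevated_dbp`, `htn_sbp`, `htn_dbp`.
#' @export
default_static_rules <- function() {
  data.frame(
    guideline    = c("aap_2017", "aap_2017", "fourth_2004"),
    age_min_years = c(13L, 18L, 18L),
    age_max_years = c(17L, 20L, 20L),
    elevated_sbp = c(120, 120, 120),
    elevated_dbp = c(80, 80, 80),
    htn_sbp      = c(130, 140, 140),
    htn_dbp      = c(80, 90, 90),
    stringsAsFactors = FALSE
  )
}

static_rule_for <- function(static_rules, guideline, age_years) {
  hit <- static_rules[static_rules$guideline == guideline &
                        static_rules$age_min_years <= age_years &
                        static_rules$age_max_years >= age_years, ]
  if (nrow(hit) > 1) pedhtn_stop("overlapping static rules", "table_error")
  hit
}

#' Resolve guideline BP thresholds for one person-visit context
#'
#' Turns the guideline classification rules into a numeric threshold set
#' (elevated and hypertension cutoffs for SBP and DBP) for a child of given
#' sex, age and height percentile:
#'
#' * **2004 Fourth Report, ages 1-17**: prehypertension starts at the 90th
#'   BP percentile or 120/80 mmHg, whichever is lower; hypertension starts
#'   at the 95th percentile value + 5 mmHg.
#' * **2017 AAP, ages 1-12**: elevated starts at min(90th percentile,
#'   120/80); hypertension at min(95th percentile, 130/80).
#' * **2017 AAP, ages 13-17**: static 120/80 (elevated) and 130/80
#'   (hypertension), independent of sex and height.
#' * **Both guidelines, ages 18-20**: adult rule, hypertension at 140/90
#'   with the 120/80 elevated floor.
#'
#' @inheritParams bp_percentile_value
#' @param tables BP reference table (needed for percentile-based ages).
#' @param static_rules static rules, default [default_static_rules()].
#' @return a one-row data.frame (threshold set) with columns
#'   `elevated_sbp`, `elevated_dbp`, `htn_sbp`, `htn_dbp`, `provenance`
#'   (`"percentile"`, `"static"` or `"min_of_both"`).
#' @export
#' @examples
#' resolve_thresholds("aap_2017", "male", 15, 50, tables = NULL)
resolve_thresholds <- function(guideline, sex, age_years, height_pct,
                               tables, static_rules = default_static_rules()) {
  if (!guideline %in% GUIDELINES) {
    pedhtn_stop(paste0("unknown guideline: ", guideline), "invalid_parameter")
  }
  if (is.na(age_years) || age_years < 1 || age_years > 20) {
    pedhtn_stop(paste0("age_years must be in [1, 20], got ", age_years),
                "invalid_parameter")
  }
  rule <- static_rule_for(static_rules, guideline, age_years)
  if (nrow(rule) == 1) {
    ts <- data.frame(elevated_sbp = rule$elevated_sbp, elevated_dbp = rule$elevated_dbp,
                     htn_sbp = rule$htn_sbp, htn_dbp = rule$htn_dbp,
                     provenance = "static", stringsAsFactors = FALSE)
  } else {
    p90s <- bp_percentile_value(tables, guideline, sex, age_years, height_pct, "SBP", 90)
    p90d <- bp_percentile_value(tables, guideline, sex, age_years, height_pct, "DBP", 90)
    p95s <- bp_percentile_value(tables, guideline, sex, age_years, height_pct, "SBP", 95)
    p95d <- bp_percentile_value(tables, guideline, sex, age_years, height_pct, "DBP", 95)
    if (guideline == "fourth_2004") {
      ts <- data.frame(
        elevated_sbp = pmin(p90s, 120), elevated_dbp = pmin(p90d, 80),
        htn_sbp = p95s + 5, htn_dbp = p95d + 5,
        provenance = "min_of_both", stringsAsFactors = FALSE
      )
    } else {
      ts <- data.frame(
        elevated_sbp = pmin(p90s, 120), elevated_dbp = pmin(p90d, 80),
        htn_sbp = pmin(p95s, 130), htn_dbp = pmin(p95d, 80),
        provenance = "min_of_both", stringsAsFactors = FALSE
      )
    }
  }
  stopifnot(ts$elevated_sbp <= ts$htn_sbp, ts$elevated_dbp <= ts$htn_dbp)
  ts
}

# Vectorized threshold resolution for a data.frame of visit contexts with
# columns guideline, sex, age_years, height_pct. Returns the four threshold
# columns aligned with the input rows. Grid lookups are grouped by
# (guideline, sex, age_years) so each table subset is interpolated once.
resolve_thresholds_batch <- function(ctx, tables,
                                     static_rules = default_static_rules()) {
  n <- nrow(ctx)
  out <- data.frame(elevated_sbp = rep(NA_real_, n), elevated_dbp = NA_real_,
                    htn_sbp = NA_real_, htn_dbp = NA_real_)
  if (!n) return(out)
  if (any(ctx$age_years < 1 | ctx$age_years > 20)) {
    pedhtn_stop("age_years must be in [1, 20] for threshold resolution",
                "invalid_parameter")
  }
  key <- paste(ctx$guideline, ctx$sex, ctx$age_years, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    g <- ctx$guideline[idx[1]]; s <- ctx$sex[idx[1]]; a <- ctx$age_years[idx[1]]
    rule <- static_rule_for(static_rules, g, a)
    if (nrow(rule) == 1) {
      out$elevated_sbp[idx] <- rule$elevated_sbp
      out$elevated_dbp[idx] <- rule$elevated_dbp
      out$htn_sbp[idx] <- rule$htn_sbp
      out$htn_dbp[idx] <- rule$htn_dbp
    } else {
      h <- ctx$height_pct[idx]
      out$elevated_sbp[idx] <- pmin(bp_percentile_value(tables, g, s, a, h, "SBP", 90), 120)
      out$elevated_dbp[idx] <- pmin(bp_percentile_value(tables, g, s, a, h, "DBP", 90), 80)
      if (g == "fourth_2004") {
        out$htn_sbp[idx] <- bp_percentile_value(tables, g, s, a, h, "SBP", 95) + 5
        out$htn_dbp[idx] <- bp_percentile_value(tables, g, s, a, h, "DBP", 95) + 5
      } else {
        out$htn_sbp[idx] <- pmin(bp_percentile_value(tables, g, s, a, h, "SBP", 95), 130)
        out$htn_dbp[idx] <- pmin(bp_percentile_value(tables, g, s, a, h, "DBP", 95), 80)
      }
    }
  }
  stopifnot(all(out$elevated_sbp <= out$htn_sbp),
            all(out$elevated_dbp <= out$htn_dbp))
  out
}
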