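#' Read a PMCA ICD code map
#'
#' Delimited text with a header row and columns `icd_version` (9 or 10),
#' `code_prefix`, `body_system` (one of the 18 [PMCA_BODY_SYSTEMS]),
#' `progressive` (logical), `malignancy` (logical). Codes are matched to
#' map entries by longest prefix within the ICD version. `(icd_version,
#' code_prefix)` pairs must be unique.
#'
#' The full published PMCA v2.0 code lists are a user-supplied plug-in;
#' [gen_code_map()] ships a synthetic map with the same structure for tests.
#'
#' @param file path to a delimited text file.
#' @param sep field separator (default comma).
#' @return validated `data.frame` code map.
#' @export
read_code_map <- function(file, sep = ",") {
  df <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE)
  validate_code_map(df)
}

#' @rdname read_code_map
#' @param df a data.frame with the code-map columns.
#' @export
validate_code_map <- function(df) {
  need <- c("icd_version", "code_prefix", "body_system", "progressive", "malignancy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pedhtn_stop(paste0("code map: missing column(s) ",
                       paste(missing_cols, collapse = ", ")), "table_error")
  }
  if (any(!nzchar(df$code_prefix))) {
    pedhtn_stop(paste0("code map: empty code_prefix at row ",
                       which(!nzchar(df$code_prefix))[1]), "table_error")
  }
  dup <- duplicated(df[, c("icd_version", "code_prefix")])
  if (any(dup)) {
    pedhtn_stop(paste0("code map: duplicate (icd_version, code_prefix) at row ",
                       which(dup)[1]), "table_error")
  }
  bad <- !df$body_system %in% PMCA_BODY_SYSTEMS
  if (any(bad)) {
    pedhtn_stop(paste0("code map: unknown body_system '", df$body_system[bad][1],
                       "' at row ", which(bad)[1]), "table_error")
  }
  df$progressive <- as.logical(df$progressive)
  df$malignancy <- as.logical(df$malignancy)
  df
}

#' Read a diagnosis encounter file
#'
#' Delimited text with a header row and columns `person_id`, `date`
#' (ISO-8601), `setting` (`outpatient`, `emergency`,
#' `inpatient_discharge`), `icd_version`, `code`.
#'
#' @inheritParams read_code_map
#' @return data.frame of encounters with a `Date` date column.
#' @export
read_encounters <- function(file, sep = ",") {
  df <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("person_id", "date", "setting", "icd_version", "code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pedhtn_stop(paste0("encounter file: missing column(s) ",
                       paste(missing_cols, collapse = ", ")), "table_error")
  }
  df$date <- as.Date(df$date)
  df
}

# Longest-prefix match of codes against the map, per ICD version.
# Returns the map row index for each code (NA when unmapped).
match_codes <- function(icd_version, code, code_map) {
  out <- rep(NA_integer_, length(code))
  for (v in unique(code_map$icd_version)) {
    rows <- which(code_map$icd_version == v)
    prefs <- code_map$code_prefix[rows]
    ord <- order(nchar(prefs), decreasing = TRUE) # longest prefix wins
    cand <- which(icd_version == v & is.na(out))
    for (j in ord) {
      if (!length(cand)) break
      hit <- startsWith(code[cand], prefs[j])
      out[cand[hit]] <- rows[j]
      cand <- cand[!hit]
    }
  }
  out
}

#' Conditions qualifying in the lookback window
#'
#' A condition (a code-map entry group keyed by body system and its
#' progressive/malignancy flags) qualifies for one person when, within the
#' half-open lookback window `[index_date - lookback_days, index_date)`,
#' mapped codes for it appear on at least two distinct encounter dates in
#' outpatient/emergency settings, or on at least one inpatient-discharge
#' record. Unmapped codes are ignored and tallied in the `n_unmapped`
#' attribute.
#'
#' @param encounters encounter data.frame for one person (see
#'   [read_encounters()]).
#' @param code_map PMCA code map (see [read_code_map()]).
#' @param index_date anchor date (e.g. first outpatient BP visit of the
#'   person-year).
#' @param lookback_days window length in days (default 365).
#' @return data.frame of qualified conditions (`body_system`,
#'   `progressive`, `malignancy`), with attribute `n_unmapped`.
#' @export
qualified_conditions <- function(encounters, code_map, index_date,
                                 lookback_days = 365) {
  index_date <- as.Date(index_date)
  win <- encounters[encounters$date >= index_date - lookback_days &
                      encounters$date < index_date, , drop = FALSE]
  empty <- data.frame(body_system = character(0), progressive = logical(0),
                      malignancy = logical(0), stringsAsFactors = FALSE)
  if (!nrow(win)) return(structure(empty, n_unmapped = 0L))
  m <- match_codes(win$icd_version, win$code, code_map)
  n_unmapped <- sum(is.na(m))
  win <- win[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  if (!nrow(win)) return(structure(empty, n_unmapped = n_unmapped))
  cond <- paste(code_map$body_system[m], code_map$progressive[m],
                code_map$malignancy[m], sep = "|")
  qual <- vapply(split(seq_along(cond), cond), function(idx) {
    inpatient <- win$setting[idx] == "inpatient_discharge"
    outp <- idx[!inpatient]
    any(inpatient) || length(unique(win$date[outp])) >= 2
  }, logical(1))
  keys <- do.call(rbind, strsplit(names(qual)[qual], "|", fixed = TRUE))
  if (is.null(keys)) return(structure(empty, n_unmapped = n_unmapped))
  structure(data.frame(body_system = keys[, 1],
                       progressive = as.logical(keys[, 2]),
                       malignancy = as.logical(keys[, 3]),
                       stringsAsFactors = FALSE),
            n_unmapped = n_unmapped)
}

#' Medical complexity level from qualified conditions
#'
#' Conservative Pediatric Medical Complexity Algorithm criteria: complex
#' chronic disease when conditions span at least two distinct body systems,
#' or any qualified condition is progressive or a malignancy; non-complex
#' chronic disease when exactly one body system qualifies and neither flag
#' is set; otherwise without chronic disease.
#'
#' @param qualified data.frame from [qualified_conditions()].
#' @return list: `level` (`"complex_cd"`, `"non_complex_cd"`,
#'   `"without_cd"`), `body_systems` (character vector), `progressive`,
#'   `malignancy` (logicals).
#' @export
pmca_level <- function(qualified) {
  systems <- unique(qualified$body_system)
  progressive <- any(qualified$progressive)
  malignancy <- any(qualified$malignancy)
  level <- if (length(systems) >= 2 || progressive || malignancy) {
    "complex_cd"
  } else if (length(systems) == 1) {
    "non_complex_cd"
  } else {
    "without_cd"
  }
  list(level = level, body_systems = systems,
       progressive = progressive, malignancy = malignancy)
}

#' Classify medical complexity for every person
#'
#' Applies [qualified_conditions()] and [pmca_level()] per person at a
#' per-person index date.
#'
#' @param encounters encounter data.frame (all persons).
#' @param code_map PMCA code map.
#' @param index_dates data.frame with columns `person_id`, `index_date`.
#' @param lookback_days window length in days (default 365).
#' @return data.frame: `person_id`, `index_date`, `level`, `n_systems`,
#'   `progressive`, `malignancy`, `body_systems` (comma-joined).
#' @export
classify_pmca <- function(encounters, code_map, index_dates,
                          lookback_days = 365) {
  res <- lapply(seq_len(nrow(index_dates)), function(i) {
    pid <- index_dates$person_id[i]
    enc <- encounters[encounters$person_id == pid, , drop = FALSE]
    q <- qualified_conditions(enc, code_map, index_dates$index_date[i],
                              lookback_days)
    lv <- pmca_level(q)
    data.frame(person_id = pid,
               index_date = as.Date(index_dates$index_date[i]),
               level = lv$level, n_systems = length(lv$body_systems),
               progressive = lv$progressive, malignancy = lv$malignancy,
               body_systems = paste(sort(lv$body_systems), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Healthcare utilization in the lookback window
#'
#' Counts outpatient visits, emergency-department visits, and
#' hospitalizations (one per inpatient-discharge record) for one person in
#' the half-open window `[index_date - lookback_days, index_date)`.
#'
#' @inheritParams qualified_conditions
#' @return named integer vector `c(outpatient, emergency, hospitalization)`.
#' @export
utilization_summary <- function(encounters, index_date, lookback_days = 365) {
  index_date <- as.Date(index_date)
  win <- encounters[encounters$date >= index_date - lookback_days &
                      encounters$date < index_date, , drop = FALSE]
  c(outpatient = sum(win$setting == "outpatient"),
    emergency = sum(win$setting == "emergency"),
    hospitalization = sum(win$setting == "inpatient_discharge"))
}
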