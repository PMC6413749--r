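# Longitudinal biomarker cohort container and I/O.

COHORT_CORE_COLS <- c("species", "individual_id", "sex", "age_at_obs",
                      "population", "death_age", "body_mass")

#' Construct a longitudinal biomarker cohort table
#'
#' A `cohort_table` is a data frame with one row per individual-visit, core
#' columns `species`, `individual_id`, `sex`, `age_at_obs`, and optional
#' `population`, `death_age`, `body_mass`, plus one numeric column per
#' biomarker. Invariants enforced: positive observation ages, death age (when
#' present) at or after the individual's last observation, one species and one
#' sex per individual, and finite marker values where present.
#'
#' @param data A data frame holding core and marker columns.
#' @param markers Character vector naming the marker columns in `data`.
#' @param validate Check invariants and drop violating rows (default `TRUE`).
#' @return A `cohort_table` (data frame) with attributes `markers` and
#'   `validation` (a log of dropped rows / flagged columns).
#' @export
cohort_table <- function(data, markers, validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_core <- setdiff(c("species", "individual_id", "sex", "age_at_obs"),
                          names(data))
  if (length(missing_core) > 0) {
    stop_dysreg(paste0("missing required column(s): ",
                       paste(missing_core, collapse = ", ")),
                "dysregkit_schema_error")
  }
  missing_markers <- setdiff(markers, names(data))
  if (length(missing_markers) > 0) {
    stop_dysreg(paste0("marker column(s) absent: ",
                       paste(missing_markers, collapse = ", ")),
                "dysregkit_schema_error")
  }
  if (!"population" %in% names(data)) data$population <- "pop1"
  if (!"death_age" %in% names(data)) data$death_age <- NA_real_
  if (!"body_mass" %in% names(data)) data$body_mass <- NA_real_

  data$species <- as.character(data$species)
  data$individual_id <- as.character(data$individual_id)
  data$sex <- normalize_sex(data$sex)
  data$population <- as.character(data$population)
  for (col in c("age_at_obs", "death_age", "body_mass", markers)) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  log <- list(rows_dropped = 0L, row_log = character(0),
              all_missing_markers = character(0))
  if (validate) {
    bad_age <- !is.finite(data$age_at_obs) | data$age_at_obs <= 0
    if (any(bad_age)) {
      log$row_log <- c(log$row_log, sprintf(
        "row %d: invalid age_at_obs (%s)", which(bad_age),
        data$age_at_obs[bad_age]))
      data <- data[!bad_age, , drop = FALSE]
    }
    # death before an observed visit is an impossible record
    last_obs <- tapply(data$age_at_obs, data$individual_id, max)
    death <- tapply(data$death_age, data$individual_id,
                    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    bad_ids <- names(last_obs)[!is.na(death) & death < last_obs - 1e-12]
    if (length(bad_ids) > 0) {
      drop <- data$individual_id %in% bad_ids
      log$row_log <- c(log$row_log, sprintf(
        "individual %s: death_age precedes an observation; rows dropped",
        bad_ids))
      data <- data[!drop, , drop = FALSE]
    }
    # one species / sex per individual
    for (field in c("species", "sex")) {
      n_lev <- tapply(data[[field]], data$individual_id,
                      function(v) length(unique(v)))
      multi <- names(n_lev)[n_lev > 1]
      if (length(multi) > 0) {
        stop_dysreg(paste0("individual(s) mapped to multiple ", field,
                           " values: ", paste(multi, collapse = ", ")),
                    "dysregkit_input_error")
      }
    }
    for (mk in markers) {
      inf <- is.infinite(data[[mk]])
      if (any(inf)) data[[mk]][inf] <- NA_real_
      if (all(is.na(data[[mk]]))) {
        log$all_missing_markers <- c(log$all_missing_markers, mk)
      }
    }
    log$rows_dropped <- length(log$row_log)
  }
  rownames(data) <- NULL
  structure(data,
            markers = as.character(markers),
            validation = log,
            class = c("cohort_table", "data.frame"))
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out
}

#' List the marker columns of a cohort
#' @param cohort A `cohort_table`.
#' @return Character vector of marker names.
#' @export
markers <- function(cohort) attr(cohort, "markers")

set_markers <- function(cohort, new_markers) {
  attr(cohort, "markers") <- new_markers
  cohort
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d observations, %d individuals, %d species, %d markers\n",
              nrow(x), length(unique(x$individual_id)),
              length(unique(x$species)), length(markers(x))))
  NextMethod()
}

#' Read a longitudinal biomarker cohort from CSV
#'
#' Reads a long-format CSV (one row per individual-visit), maps columns via
#' `schema`, validates invariants, and logs rejected rows. Any numeric column
#' not named in the schema is treated as a biomarker unless `marker_cols` is
#' given.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Named character vector mapping canonical names
#'   (`species`, `individual_id`, `sex`, `age_at_obs`, and optionally
#'   `population`, `death_age`, `body_mass`) to column names in the file.
#'   Defaults to identity naming.
#' @param marker_cols Marker column names in the file; default: all columns
#'   not claimed by the schema.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, schema = NULL, marker_cols = NULL) {
  if (!file.exists(path)) {
    stop_dysreg(paste0("cohort file not found: ", path), "dysregkit_input_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop_dysreg("cohort file is empty", "dysregkit_input_error")
  canonical <- COHORT_CORE_COLS
  required <- c("species", "individual_id", "sex", "age_at_obs")
  if (is.null(schema)) {
    # identity schema: optional core columns only when present in the file
    schema <- stats::setNames(canonical, canonical)
    schema <- schema[schema %in% names(raw) | names(schema) %in% required]
  }
  have <- intersect(names(schema), canonical)
  miss_req <- setdiff(required, have)
  if (length(miss_req) > 0) {
    stop_dysreg(paste0("schema does not map required field(s): ",
                       paste(miss_req, collapse = ", ")),
                "dysregkit_schema_error")
  }
  absent <- schema[have][!schema[have] %in% names(raw)]
  if (length(absent) > 0) {
    stop_dysreg(paste0("column(s) missing from file: ",
                       paste(absent, collapse = ", ")),
                "dysregkit_schema_error")
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (fld in have) df[[fld]] <- raw[[schema[[fld]]]]
  if (is.null(marker_cols)) {
    marker_cols <- setdiff(names(raw), unname(schema[have]))
  }
  for (mk in marker_cols) df[[mk]] <- raw[[mk]]
  cohort_table(df, markers = marker_cols)
}

#' Write a cohort to CSV
#'
#' Round-trips numeric cells bit-exactly through full-precision decimal text.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validation report of a cohort
#' @param cohort A `cohort_table`.
#' @return List with dropped-row log and all-missing marker flags.
#' @export
validation_report <- function(cohort) attr(cohort, "validation")

#' Construct species metadata
#'
#' Holds per-species maturation ages (adult filter thresholds), optional
#' expected maximum lifespans, and per-marker plausibility bounds used to
#' screen biologically improbable values.
#'
#' @param species Character vector of species labels.
#' @param maturation_age Numeric vector, years; must be positive.
#' @param expected_max_lifespan Optional numeric vector, years.
#' @param bounds Optional data frame with columns `species` (or `NA` for all
#'   species), `marker`, `low`, `high`; open interval, `low < high`.
#' @return A `species_meta` object.
#' @export
species_meta <- function(species, maturation_age, expected_max_lifespan = NA_real_,
                         bounds = NULL) {
  stopifnot(length(species) == length(maturation_age))
  if (any(!is.finite(maturation_age) | maturation_age <= 0)) {
    stop_dysreg("maturation_age must be positive", "dysregkit_config_error")
  }
  if (!is.null(bounds)) {
    stopifnot(all(c("marker", "low", "high") %in% names(bounds)))
    if (!"species" %in% names(bounds)) bounds$species <- NA_character_
    if (any(bounds$low >= bounds$high)) {
      stop_dysreg("plausibility bounds must satisfy low < high",
                  "dysregkit_config_error")
    }
  }
  structure(list(
    species = data.frame(species = as.character(species),
                         maturation_age = as.numeric(maturation_age),
                         expected_max_lifespan =
                           rep_len(as.numeric(expected_max_lifespan),
                                   length(species)),
                         stringsAsFactors = FALSE),
    bounds = bounds
  ), class = "species_meta")
}
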