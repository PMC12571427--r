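## Patient-level EHR data model: table contracts, validation and CSV I/O.

SEX_LEVELS <- c("female", "male")
RACE_LEVELS <- c("african_american", "asian", "hispanic", "white", "other")
SETTING_LEVELS <- c("inpatient", "outpatient", "emergency")
DX_SETTING_LEVELS <- c("inpatient", "outpatient")
CODE_SYSTEMS <- c("ICD9", "ICD10")
ANALYTES <- c("hba1c", "fasting_glucose", "random_glucose", "c_peptide",
              "diabetes_autoantibody")
NUMERIC_ANALYTES <- setdiff(ANALYTES, "diabetes_autoantibody")
EVENT_TYPES <- c("prescribed", "dispensed", "administered")

BUNDLE_TABLES <- c("patients", "encounters", "diagnoses", "labs",
                   "medications", "pregnancies")

bundle_columns <- list(
  patients     = c("patient_id", "birth_date", "sex", "race_ethnicity"),
  encounters   = c("patient_id", "date", "system_id", "setting"),
  diagnoses    = c("patient_id", "date", "code_system", "code", "setting"),
  labs         = c("patient_id", "date", "analyte", "value", "units"),
  medications  = c("patient_id", "date", "ingredient", "event_type"),
  pregnancies  = c("patient_id", "start_date", "end_date")
)

empty_table <- function(name) {
  cols <- bundle_columns[[name]]
  out <- data.table::as.data.table(
    stats::setNames(rep(list(character(0)), length(cols)), cols))
  for (col in intersect(cols, c("birth_date", "date", "start_date", "end_date"))) {
    data.table::set(out, j = col, value = as.Date(character(0)))
  }
  out
}

#' Construct a validated EHR bundle
#'
#' An `ehr_bundle` holds the six patient-level tables (patients, encounters,
#' diagnoses, labs, medications, pregnancies) plus `cp1_systems`, the set of
#' `system_id` values making up CP 1's restricted two-health-system
#' catchment.  All diagnosis codes are normalized (see [normalize_code()])
#' and every invariant of the data model is checked.
#'
#' @param patients,encounters,diagnoses,labs,medications,pregnancies
#'   Data frames following the documented column contract.  Missing tables
#'   default to empty.
#' @param cp1_systems Character vector of system ids; must be a subset of the
#'   systems observed in `encounters` (or empty).
#' @return A list of class `ehr_bundle`.
#' @export
ehr_bundle <- function(patients = NULL, encounters = NULL, diagnoses = NULL,
                       labs = NULL, medications = NULL, pregnancies = NULL,
                       cp1_systems = character(0)) {
  tabs <- list(patients = patients, encounters = encounters,
               diagnoses = diagnoses, labs = labs,
               medications = medications, pregnancies = pregnancies)
  for (name in BUNDLE_TABLES) {
    tb <- tabs[[name]]
    if (is.null(tb)) {
      tabs[[name]] <- empty_table(name)
      next
    }
    tb <- data.table::as.data.table(tb)
    missing_cols <- setdiff(bundle_columns[[name]], names(tb))
    if (length(missing_cols)) {
      stop(sprintf("table '%s': missing column(s) %s", name,
                   paste(sQuote(missing_cols), collapse = ", ")))
    }
    extra <- setdiff(names(tb), bundle_columns[[name]])
    if (length(extra)) {
      stop(sprintf("table '%s': unknown column(s) %s", name,
                   paste(sQuote(extra), collapse = ", ")))
    }
    tabs[[name]] <- tb[, bundle_columns[[name]], with = FALSE]
  }
  if (nrow(tabs$diagnoses)) {
    tabs$diagnoses[, code := normalize_code(code)]
  }
  bundle <- structure(c(tabs, list(cp1_systems = sort(unique(as.character(cp1_systems))))),
                      class = "ehr_bundle")
  validate_bundle(bundle)
  bundle
}

parse_iso_date <- function(x, table, column) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("table '%s', column '%s', row %d: malformed date %s",
                 table, column, bad[1], sQuote(x[bad[1]])))
  }
  out
}

check_levels <- function(x, levels, table, column) {
  bad <- which(!(x %in% levels))
  if (length(bad)) {
    stop(sprintf("table '%s', column '%s', row %d: value %s not in {%s}",
                 table, column, bad[1], sQuote(x[bad[1]]),
                 paste(levels, collapse = ", ")))
  }
}

#' Validate an EHR bundle against the data-model invariants
#'
#' Checks unique patient ids, category levels, resolvable foreign keys,
#' normalized codes, lab value typing (numeric analytes non-negative,
#' autoantibody qualitative only), non-overlapping pregnancy intervals and
#' the catchment subset condition.  Errors name the offending table and row.
#'
#' @param bundle An `ehr_bundle`.
#' @return The bundle, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  p <- bundle$patients
  if (anyDuplicated(p$patient_id)) {
    dup <- p$patient_id[duplicated(p$patient_id)][1]
    stop(sprintf("table 'patients': duplicated patient_id %s", sQuote(dup)))
  }
  check_levels(p$sex, SEX_LEVELS, "patients", "sex")
  check_levels(p$race_ethnicity, RACE_LEVELS, "patients", "race_ethnicity")
  if (anyNA(p$birth_date)) stop("table 'patients': missing birth_date")

  ids <- p$patient_id
  fk_tables <- c("encounters", "diagnoses", "labs", "medications", "pregnancies")
  for (name in fk_tables) {
    tb <- bundle[[name]]
    if (!nrow(tb)) next
    bad <- which(!(tb$patient_id %in% ids))
    if (length(bad)) {
      stop(sprintf("table '%s', row %d: unknown patient_id %s",
                   name, bad[1], sQuote(tb$patient_id[bad[1]])))
    }
  }

  e <- bundle$encounters
  if (nrow(e)) check_levels(e$setting, SETTING_LEVELS, "encounters", "setting")
  d <- bundle$diagnoses
  if (nrow(d)) {
    check_levels(d$code_system, CODE_SYSTEMS, "diagnoses", "code_system")
    check_levels(d$setting, DX_SETTING_LEVELS, "diagnoses", "setting")
    bad <- which(!grepl("^[A-Z0-9]+$", d$code))
    if (length(bad)) {
      stop(sprintf("table 'diagnoses', row %d: malformed code %s",
                   bad[1], sQuote(d$code[bad[1]])))
    }
  }
  l <- bundle$labs
  if (nrow(l)) {
    check_levels(l$analyte, ANALYTES, "labs", "analyte")
    num <- l$analyte %in% NUMERIC_ANALYTES
    vals <- suppressWarnings(as.numeric(l$value))
    bad <- which(num & (is.na(vals) | vals < 0))
    if (length(bad)) {
      stop(sprintf("table 'labs', row %d: analyte '%s' needs a non-negative numeric value, got %s",
                   bad[1], l$analyte[bad[1]], sQuote(as.character(l$value[bad[1]]))))
    }
    bad <- which(!num & !(l$value %in% c("positive", "negative")))
    if (length(bad)) {
      stop(sprintf("table 'labs', row %d: diabetes_autoantibody value must be positive/negative, got %s",
                   bad[1], sQuote(as.character(l$value[bad[1]]))))
    }
  }
  m <- bundle$medications
  if (nrow(m)) {
    check_levels(m$event_type, EVENT_TYPES, "medications", "event_type")
    bad <- which(!nzchar(m$ingredient) | m$ingredient != tolower(m$ingredient))
    if (length(bad)) {
      stop(sprintf("table 'medications', row %d: ingredient must be non-empty lowercase, got %s",
                   bad[1], sQuote(m$ingredient[bad[1]])))
    }
  }
  pr <- bundle$pregnancies
  if (nrow(pr)) {
    bad <- which(pr$start_date > pr$end_date)
    if (length(bad)) {
      stop(sprintf("table 'pregnancies', row %d: start_date after end_date", bad[1]))
    }
    prs <- pr[order(patient_id, start_date)]
    overlap <- prs[, if (.N > 1L) any(start_date[-1] <= end_date[-.N]) else FALSE,
                   by = patient_id]
    if (any(overlap$V1)) {
      stop(sprintf("table 'pregnancies': overlapping intervals for patient %s",
                   sQuote(overlap$patient_id[which(overlap$V1)[1]])))
    }
  }
  if (length(bundle$cp1_systems)) {
    observed <- unique(e$system_id)
    extra <- setdiff(bundle$cp1_systems, observed)
    if (length(extra)) {
      stop("cp1_systems not observed in encounters: ",
           paste(sQuote(extra), collapse = ", "))
    }
  }
  invisible(bundle)
}

#' Read an EHR bundle from a directory of CSV tables
#'
#' Expects `patients.csv`, `encounters.csv`, `diagnoses.csv`, `labs.csv`,
#' `medications.csv` and `pregnancies.csv` (comma-separated, UTF-8, header
#' row, ISO-8601 dates), plus an optional `cp1_systems.txt` (one system id
#' per line).  When `cp1_systems.txt` is absent every observed system is
#' treated as in-catchment.
#'
#' @param dir Directory containing the tables, or a named character vector /
#'   list of per-table file paths (names as above, without `.csv`).
#' @return A validated `ehr_bundle`.
#' @export
load_bundle <- function(dir) {
  if (length(dir) == 1L && is.null(names(dir))) {
    paths <- stats::setNames(file.path(dir, paste0(BUNDLE_TABLES, ".csv")),
                             BUNDLE_TABLES)
    systems_path <- file.path(dir, "cp1_systems.txt")
  } else {
    paths <- unlist(dir[BUNDLE_TABLES])
    systems_path <- if ("cp1_systems" %in% names(dir)) dir[["cp1_systems"]] else ""
  }
  tabs <- list()
  for (name in BUNDLE_TABLES) {
    path <- paths[[name]]
    if (is.null(path) || !file.exists(path)) {
      stop(sprintf("table '%s': file not found: %s", name, path))
    }
    tb <- data.table::fread(path, colClasses = "character",
                            na.strings = NULL, encoding = "UTF-8")
    if (!nrow(tb) && !length(names(tb))) tb <- empty_table(name)
    for (col in intersect(names(tb), c("birth_date", "date", "start_date", "end_date"))) {
      data.table::set(tb, j = col, value = parse_iso_date(tb[[col]], name, col))
    }
    tabs[[name]] <- tb
  }
  cp1_systems <- character(0)
  if (nzchar(systems_path) && file.exists(systems_path)) {
    cp1_systems <- readLines(systems_path, warn = FALSE)
    cp1_systems <- cp1_systems[nzchar(cp1_systems)]
  }
  ehr_bundle(patients = tabs$patients, encounters = tabs$encounters,
             diagnoses = tabs$diagnoses, labs = tabs$labs,
             medications = tabs$medications, pregnancies = tabs$pregnancies,
             cp1_systems = cp1_systems)
}

#' Write an EHR bundle to a directory of CSV tables
#'
#' Inverse of [load_bundle()]: writes the six tables plus `cp1_systems.txt`.
#' `load_bundle(write_bundle(b, dir))` reproduces `b` field for field.
#'
#' @param bundle An `ehr_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in BUNDLE_TABLES) {
    data.table::fwrite(bundle[[name]], file.path(dir, paste0(name, ".csv")))
  }
  writeLines(bundle$cp1_systems, file.path(dir, "cp1_systems.txt"))
  invisible(dir)
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>\n")
  for (name in BUNDLE_TABLES) {
    cat(sprintf("  %-12s %d rows\n", name, nrow(x[[name]])))
  }
  cat(sprintf("  cp1_systems  {%s}\n", paste(x$cp1_systems, collapse = ", ")))
  invisible(x)
}

## All records for one patient, as a bundle-shaped list (used by the
## single-patient phenotype operations).
patient_view <- function(bundle, patient_id) {
  id <- patient_id
  out <- lapply(bundle[BUNDLE_TABLES], function(tb) tb[tb$patient_id == id, ])
  out$cp1_systems <- bundle$cp1_systems
  out
}
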