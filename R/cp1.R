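## Computable phenotype 1: diabetes detection from labs, diagnosis codes and
## prescriptions, followed by type 1 exclusion rules; remaining cases are T2D.

#' Closed calendar-date window ending with a prevalence year
#'
#' @param prevalence_year Integer year whose prevalence is being measured.
#' @param n_years Number of calendar years covered, including
#'   `prevalence_year` (2 for CP 1, 3 for CP 2).
#' @return Date vector `c(start, end)`:
#'   `[Jan 1 of (year - n_years + 1), Dec 31 of year]`.
#' @export
calendar_window <- function(prevalence_year, n_years) {
  prevalence_year <- as.integer(prevalence_year)
  c(as.Date(sprintf("%d-01-01", prevalence_year - n_years + 1L)),
    as.Date(sprintf("%d-12-31", prevalence_year)))
}

as_window <- function(window) {
  window <- as.Date(window)
  if (length(window) != 2L || anyNA(window) || window[1] > window[2]) {
    stop("window must be c(start, end) with start <= end")
  }
  window
}

lab_numeric <- function(labs) suppressWarnings(as.numeric(labs$value))

## Abnormal-lab flag per lab row under the shared thresholds.
abnormal_lab_flag <- function(labs, criteria) {
  v <- lab_numeric(labs)
  (labs$analyte == "hba1c" & v >= criteria$hba1c_threshold) |
    (labs$analyte == "fasting_glucose" & v >= criteria$fasting_glucose_threshold) |
    (labs$analyte == "random_glucose" & v >= criteria$random_glucose_threshold)
}

## Qualifying diabetes diagnosis rows for CP 1 (code-system aware).
cp1_dx_flag <- function(dx, criteria) {
  (dx$code_system == "ICD9" & code_matches_any(dx$code, criteria$dx_patterns_icd9)) |
    (dx$code_system == "ICD10" & code_matches_any(dx$code, criteria$dx_patterns_icd10))
}

## Type-specific code flags shared by both phenotypes: ICD-10 E10.x and
## ICD-9 fifth digits 1/3 are type 1; ICD-10 E11.x and fifth digits 0/2 are
## type 2.  Other diabetes codes count toward neither side of the ratio.
t1d_type_flag <- function(dx) {
  (dx$code_system == "ICD10" & code_matches(dx$code, "E10.x")) |
    (dx$code_system == "ICD9" & code_matches_any(dx$code, ICD9_T1D_PATTERNS))
}
t2d_type_flag <- function(dx) {
  (dx$code_system == "ICD10" & code_matches(dx$code, "E11.x")) |
    (dx$code_system == "ICD9" & code_matches_any(dx$code, ICD9_T2D_PATTERNS))
}

in_window <- function(date, window) date >= window[1] & date <= window[2]

## Prescribed-medication rows restricted to the window (CP 1 reads
## "prescription" literally: dispense/administration events do not count).
cp1_rx <- function(meds, window) {
  meds[meds$event_type == "prescribed" & in_window(meds$date, window), ]
}

## Per-patient criterion flags for CP 1 over an arbitrary record set.
## Returns one row per patient id in `ids` with logical clause columns.
cp1_flags <- function(tables, ids, window, criteria) {
  out <- data.table::data.table(patient_id = ids)

  labs <- tables$labs[in_window(tables$labs$date, window), ]
  if (nrow(labs)) {
    ab <- labs[abnormal_lab_flag(labs, criteria), ]
    if (criteria$lab_occasions_mode == "pooled") {
      hit <- ab[, .(lab_ok = data.table::uniqueN(date) >= criteria$min_occasions),
                by = patient_id]
    } else {
      per <- ab[, .(n_dates = data.table::uniqueN(date)),
                by = .(patient_id, analyte)]
      hit <- per[, .(lab_ok = any(n_dates >= criteria$min_occasions)),
                 by = patient_id]
    }
    out <- merge(out, hit, by = "patient_id", all.x = TRUE)
  } else out[, lab_ok := NA]

  dx <- tables$diagnoses[in_window(tables$diagnoses$date, window), ]
  if (nrow(dx)) {
    qual <- dx[cp1_dx_flag(dx, criteria), ]
    hit <- qual[, .(dx_ok = data.table::uniqueN(date) >= criteria$min_occasions),
                by = patient_id]
    out <- merge(out, hit, by = "patient_id", all.x = TRUE)
    typed <- dx[, .(t1_codes = sum(t1d_type_flag(.SD)),
                    t2_codes = sum(t2d_type_flag(.SD))),
                by = patient_id]
    out <- merge(out, typed, by = "patient_id", all.x = TRUE)
  } else out[, `:=`(dx_ok = NA, t1_codes = NA_integer_, t2_codes = NA_integer_)]

  rx <- cp1_rx(tables$medications, window)
  if (nrow(rx)) {
    ins <- rx[rx$ingredient == "insulin", ]
    if (nrow(ins) && nrow(tables$pregnancies)) {
      preg <- tables$pregnancies
      inside <- merge(ins[, .(patient_id, date)], preg,
                      by = "patient_id", allow.cartesian = TRUE)
      inside <- inside[date >= start_date & date <= end_date,
                       .(patient_id, date)]
      ins <- ins[!inside, on = c("patient_id", "date")]
    }
    if (nrow(ins)) {
      out <- merge(out, unique(ins[, .(patient_id)])[, .(patient_id, insulin_ok = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, insulin_ok := NA]
    oral <- rx[rx$ingredient %chin% criteria$noninsulin_medications, ]
    if (nrow(oral)) {
      out <- merge(out, unique(oral[, .(patient_id)])[, .(patient_id, oral_ok = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, oral_ok := NA]
    for (marker in c("urine acetone test strips", "glucagon")) {
      colname <- if (marker == "glucagon") "glucagon_rx" else "acetone_rx"
      hit <- rx[rx$ingredient == marker, ]
      if (nrow(hit)) {
        tmp <- unique(hit[, .(patient_id)])
        tmp[, (colname) := TRUE]
        out <- merge(out, tmp, by = "patient_id", all.x = TRUE)
      } else out[, (colname) := NA]
    }
  } else out[, `:=`(insulin_ok = NA, oral_ok = NA, acetone_rx = NA, glucagon_rx = NA)]

  labs_t1 <- tables$labs[in_window(tables$labs$date, window), ]
  if (nrow(labs_t1)) {
    v <- lab_numeric(labs_t1)
    cpep <- labs_t1[labs_t1$analyte == "c_peptide" &
                      !is.na(v) & v < criteria$c_peptide_t1d_threshold, ]
    if (nrow(cpep)) {
      out <- merge(out, unique(cpep[, .(patient_id)])[, .(patient_id, cpep_low = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, cpep_low := NA]
    ab <- labs_t1[labs_t1$analyte == "diabetes_autoantibody" &
                    labs_t1$value == "positive", ]
    if (nrow(ab)) {
      out <- merge(out, unique(ab[, .(patient_id)])[, .(patient_id, autoab_pos = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, autoab_pos := NA]
  } else out[, `:=`(cpep_low = NA, autoab_pos = NA)]

  for (col in setdiff(names(out), c("patient_id", "t1_codes", "t2_codes"))) {
    data.table::set(out, which(is.na(out[[col]])), col, FALSE)
  }
  for (col in c("t1_codes", "t2_codes")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out
}

## Ratio clause: T1D-type over T2D-type code counts; an all-T1D record has
## infinite ratio (passes), a record with neither type fails.
ratio_exceeds <- function(t1_codes, t2_codes, threshold) {
  data.table::fifelse(t2_codes > 0L, t1_codes / t2_codes > threshold,
                      t1_codes > 0L)
}

cp1_evidence_names <- c(
  lab_ok = "lab_2_occasions", dx_ok = "dx_2_occasions",
  insulin_ok = "insulin_outside_pregnancy", oral_ok = "noninsulin_medication",
  cpep_low = "c_peptide_low", autoab_pos = "autoantibody_positive",
  acetone_rx = "acetone_test_strips", ratio_glucagon = "ratio_glucagon",
  ratio_never_oral = "ratio_never_oral"
)

#' Detect diabetes for one patient under CP 1
#'
#' True when any of the four detection clauses holds within the window:
#' abnormal laboratory results on two or more distinct dates (pooled across
#' HbA1c >= 6.5%, fasting glucose >= 126 mg/dL, random glucose >= 200 mg/dL
#' by default), qualifying diagnosis codes (ICD-9 250.x; ICD-10 E10.x,
#' E11.x, E14.x) on two or more distinct dates, an insulin prescription
#' dated outside every pregnancy interval, or any prescription from the
#' non-insulin antidiabetic list.
#'
#' @param patient_view All records for one patient, as returned by filtering
#'   an `ehr_bundle` to one patient id (a list with the six tables).
#' @param window Closed date range `c(start, end)`; see [calendar_window()].
#' @param criteria A [cp1_criteria()] object.
#' @return `list(detected = logical, evidence = character)` where evidence
#'   names each satisfied clause.
#' @export
detect_diabetes_cp1 <- function(patient_view, window, criteria = cp1_criteria()) {
  window <- as_window(window)
  ids <- unique(c(patient_view$patients$patient_id,
                  patient_view$labs$patient_id,
                  patient_view$diagnoses$patient_id,
                  patient_view$medications$patient_id))
  if (length(ids) == 0L) return(list(detected = FALSE, evidence = character(0)))
  if (length(ids) > 1L) stop("patient_view must contain a single patient")
  fl <- cp1_flags(patient_view, ids, window, criteria)
  hits <- c("lab_ok", "dx_ok", "insulin_ok", "oral_ok")
  on <- hits[unlist(fl[1, hits, with = FALSE])]
  list(detected = length(on) > 0L, evidence = unname(cp1_evidence_names[on]))
}

#' Apply CP 1's type 1 diabetes exclusion rules to one patient
#'
#' Intended for patients already detected as diabetic.  True when any T1D
#' marker applies: C-peptide < 0.8 ng/mL, positive diabetes autoantibody,
#' a urine acetone test strip prescription, or a T1D:T2D code ratio above
#' 0.5 combined with either a glucagon prescription or the absence of any
#' non-insulin antidiabetic prescription.
#'
#' @inheritParams detect_diabetes_cp1
#' @return `list(t1d = logical, evidence = character)`.
#' @export
detect_t1d_cp1 <- function(patient_view, window, criteria = cp1_criteria()) {
  window <- as_window(window)
  ids <- unique(c(patient_view$patients$patient_id,
                  patient_view$labs$patient_id,
                  patient_view$diagnoses$patient_id,
                  patient_view$medications$patient_id))
  if (length(ids) == 0L) return(list(t1d = FALSE, evidence = character(0)))
  if (length(ids) > 1L) stop("patient_view must contain a single patient")
  fl <- cp1_flags(patient_view, ids, window, criteria)
  fl[, ratio_glucagon := ratio_exceeds(t1_codes, t2_codes, criteria$t1d_ratio_threshold) &
       glucagon_rx]
  fl[, ratio_never_oral := ratio_exceeds(t1_codes, t2_codes, criteria$t1d_ratio_threshold) &
       !oral_ok]
  hits <- c("cpep_low", "autoab_pos", "acetone_rx", "ratio_glucagon", "ratio_never_oral")
  on <- hits[unlist(fl[1, hits, with = FALSE])]
  list(t1d = length(on) > 0L, evidence = unname(cp1_evidence_names[on]))
}

#' Classify every patient in a bundle under CP 1
#'
#' Labels are exhaustive and mutually exclusive: `t2d` when diabetes is
#' detected and no T1D marker applies, `t1d` when diabetes is detected and
#' a T1D marker applies, `none` otherwise.  The lookback window is the two
#' calendar years ending with `prevalence_year`.
#'
#' @param bundle An `ehr_bundle`.
#' @param prevalence_year Integer year.
#' @param criteria A [cp1_criteria()] object.
#' @param window Optional explicit `c(start, end)` override of the default
#'   calendar window.
#' @return A `data.table` with columns `patient_id`, `label`
#'   (`none`/`t1d`/`t2d`) and `evidence` (semicolon-separated clause names).
#' @export
classify_cp1 <- function(bundle, prevalence_year, criteria = cp1_criteria(),
                         window = NULL) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  if (is.null(window)) {
    window <- calendar_window(prevalence_year, criteria$occasion_window_years)
  }
  window <- as_window(window)
  ids <- bundle$patients$patient_id
  if (length(ids) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  label = character(0), evidence = character(0)))
  }
  fl <- cp1_flags(bundle, ids, window, criteria)
  fl[, ratio_glucagon := ratio_exceeds(t1_codes, t2_codes, criteria$t1d_ratio_threshold) &
       glucagon_rx]
  fl[, ratio_never_oral := ratio_exceeds(t1_codes, t2_codes, criteria$t1d_ratio_threshold) &
       !oral_ok]
  diab <- fl$lab_ok | fl$dx_ok | fl$insulin_ok | fl$oral_ok
  t1d <- fl$cpep_low | fl$autoab_pos | fl$acetone_rx | fl$ratio_glucagon |
    fl$ratio_never_oral
  label <- data.table::fifelse(!diab, "none",
                               data.table::fifelse(t1d, "t1d", "t2d"))
  ev <- rep("", length(ids))
  for (col in names(cp1_evidence_names)) {
    sel <- which(diab & fl[[col]])
    ev[sel] <- ifelse(nzchar(ev[sel]),
                      paste0(ev[sel], ";", cp1_evidence_names[[col]]),
                      cp1_evidence_names[[col]])
  }
  data.table::data.table(patient_id = ids, label = label, evidence = ev)
}
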