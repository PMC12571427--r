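## Computable phenotype 2: wide-net candidate identification, codes-only DM
## confirmation, then T2D classification from the type-1 code share.

## DM diagnosis rows for CP 2.  The printed ICD-9 patterns carry type 2
## fifth digits only; type-1 fifth digits (250.x1/250.x3) are included so
## the "type 1 diagnosis codes" numerator is a subset of the DM denominator.
cp2_dm_flag <- function(dx, criteria) {
  (dx$code_system == "ICD9" &
     (code_matches_any(dx$code, criteria$dm_dx_patterns_icd9) |
        code_matches_any(dx$code, ICD9_T1D_PATTERNS))) |
    (dx$code_system == "ICD10" & code_matches_any(dx$code, criteria$dm_dx_patterns_icd10))
}

cp2_t1_flag <- function(dx) {
  (dx$code_system == "ICD10" & code_matches(dx$code, "E10.x")) |
    (dx$code_system == "ICD9" & code_matches_any(dx$code, ICD9_T1D_PATTERNS))
}

## Per-patient stage flags and code counts for CP 2.
cp2_flags <- function(tables, ids, window, criteria) {
  out <- data.table::data.table(patient_id = ids)

  labs <- tables$labs[in_window(tables$labs$date, window), ]
  if (nrow(labs)) {
    ab <- labs[abnormal_lab_flag(labs, criteria), ]
    if (nrow(ab)) {
      out <- merge(out, unique(ab[, .(patient_id)])[, .(patient_id, lab_any = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, lab_any := NA]
  } else out[, lab_any := NA]

  dx <- tables$diagnoses[in_window(tables$diagnoses$date, window), ]
  if (nrow(dx)) {
    dm <- dx[cp2_dm_flag(dx, criteria), ]
    cnt <- dm[, .(dm_codes = .N, t1_codes = sum(cp2_t1_flag(.SD))), by = patient_id]
    out <- merge(out, cnt, by = "patient_id", all.x = TRUE)
  } else out[, `:=`(dm_codes = NA_integer_, t1_codes = NA_integer_)]

  meds <- tables$medications[in_window(tables$medications$date, window), ]
  if (nrow(meds)) {
    wn <- meds[meds$ingredient %chin% criteria$widenet_medications, ]
    if (nrow(wn)) {
      out <- merge(out, unique(wn[, .(patient_id)])[, .(patient_id, med_any = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, med_any := NA]
    besides <- meds[meds$ingredient %chin%
                      setdiff(criteria$widenet_medications, c("insulin", "metformin")), ]
    if (nrow(besides)) {
      out <- merge(out, unique(besides[, .(patient_id)])[, .(patient_id, besides_med = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, besides_med := NA]
    glu <- meds[meds$ingredient == "glucagon", ]
    if (nrow(glu)) {
      out <- merge(out, unique(glu[, .(patient_id)])[, .(patient_id, glucagon_any = TRUE)],
                   by = "patient_id", all.x = TRUE)
    } else out[, glucagon_any := NA]
  } else out[, `:=`(med_any = NA, besides_med = NA, glucagon_any = NA)]

  for (col in c("lab_any", "med_any", "besides_med", "glucagon_any")) {
    data.table::set(out, which(is.na(out[[col]])), col, FALSE)
  }
  for (col in c("dm_codes", "t1_codes")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, widenet := lab_any | dm_codes > 0L | med_any]
  out
}

single_patient_ids <- function(patient_view) {
  ids <- unique(c(patient_view$patients$patient_id,
                  patient_view$labs$patient_id,
                  patient_view$diagnoses$patient_id,
                  patient_view$medications$patient_id))
  if (length(ids) > 1L) stop("patient_view must contain a single patient")
  ids
}

#' Wide-net candidate test for one patient under CP 2
#'
#' True when the patient has, within the 3-year window, at least one
#' abnormal laboratory result (HbA1c >= 6.5%, fasting glucose >= 126 mg/dL
#' or random glucose >= 200 mg/dL), at least one diabetes-related diagnosis
#' code, or at least one diabetes-related medication event (prescribed,
#' dispensed or administered).
#'
#' @inheritParams detect_diabetes_cp1
#' @param criteria A [cp2_criteria()] object.
#' @return Logical scalar.
#' @export
wide_net_cp2 <- function(patient_view, window, criteria = cp2_criteria()) {
  window <- as_window(window)
  ids <- single_patient_ids(patient_view)
  if (length(ids) == 0L) return(FALSE)
  cp2_flags(patient_view, ids, window, criteria)$widenet[1]
}

#' Codes-only DM confirmation for one patient under CP 2
#'
#' Among wide-net candidates, a patient is a diabetes mellitus (DM) case
#' when at least one DM diagnosis code (ICD-9 250.x0/250.x2 plus type-1
#' fifth digits; ICD-10 E08.x, E10.x, E11.x, E13.x) appears in the window.
#'
#' @inheritParams wide_net_cp2
#' @return `list(dm = logical, t1_codes = integer, dm_codes = integer)`,
#'   the counts feeding the T2D ratio rule.
#' @export
confirm_dm_cp2 <- function(patient_view, window, criteria = cp2_criteria()) {
  window <- as_window(window)
  ids <- single_patient_ids(patient_view)
  if (length(ids) == 0L) return(list(dm = FALSE, t1_codes = 0L, dm_codes = 0L))
  fl <- cp2_flags(patient_view, ids, window, criteria)
  list(dm = fl$dm_codes[1] > 0L, t1_codes = fl$t1_codes[1], dm_codes = fl$dm_codes[1])
}

## Vectorized T2D rule over flag rows (assumes confirmed DM: dm_codes > 0).
cp2_t2d_rule <- function(fl, criteria, mode) {
  ratio_ok <- fl$t1_codes / fl$dm_codes <= criteria$t1d_ratio_threshold
  switch(mode,
         ratio_only = ratio_ok,
         or_printed = ratio_ok | fl$besides_med | !fl$glucagon_any,
         stop("unknown t2d_rule_mode: ", sQuote(mode)))
}

#' T2D classification of one confirmed DM case under CP 2
#'
#' With `mode = "ratio_only"` the patient is T2D when the ratio of type-1
#' diagnosis codes to all DM diagnosis codes is at most 0.5.  With
#' `mode = "or_printed"` (the rule as printed) the patient is T2D when the
#' ratio clause holds, OR there is any antidiabetic medication besides
#' insulin or metformin, OR there is no glucagon medication event.
#'
#' @inheritParams wide_net_cp2
#' @param mode `"or_printed"` or `"ratio_only"`; defaults to the criteria's
#'   `t2d_rule_mode`.
#' @return Logical scalar.
#' @export
classify_t2d_cp2 <- function(patient_view, window, criteria = cp2_criteria(),
                             mode = criteria$t2d_rule_mode) {
  window <- as_window(window)
  if (!mode %in% c("or_printed", "ratio_only")) {
    stop("unknown t2d_rule_mode: ", sQuote(mode))
  }
  ids <- single_patient_ids(patient_view)
  if (length(ids) == 0L) stop("patient_view has no records")
  fl <- cp2_flags(patient_view, ids, window, criteria)
  if (fl$dm_codes[1] == 0L) {
    stop("classify_t2d_cp2 requires a confirmed DM case (>= 1 DM code)")
  }
  cp2_t2d_rule(fl, criteria, mode)[1]
}

#' Classify every patient in a bundle under CP 2
#'
#' Applies the wide-net step, the codes-only DM confirmation and the T2D
#' rule over the three calendar years ending with `prevalence_year`.
#' Confirmed DM cases failing the T2D rule are labelled `t1d`; everyone
#' else outside the confirmed pool is `none`.
#'
#' @param bundle An `ehr_bundle`.
#' @param prevalence_year Integer year.
#' @param criteria A [cp2_criteria()] object.
#' @param window Optional explicit window override.
#' @return A `data.table` with columns `patient_id`, `label` and `evidence`.
#' @export
classify_cp2 <- function(bundle, prevalence_year, criteria = cp2_criteria(),
                         window = NULL) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  if (is.null(window)) {
    window <- calendar_window(prevalence_year, criteria$lookback_years)
  }
  window <- as_window(window)
  ids <- bundle$patients$patient_id
  if (length(ids) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  label = character(0), evidence = character(0)))
  }
  fl <- cp2_flags(bundle, ids, window, criteria)
  dm <- fl$widenet & fl$dm_codes > 0L
  t2d <- dm & cp2_t2d_rule(fl, criteria, criteria$t2d_rule_mode)
  label <- data.table::fifelse(t2d, "t2d", data.table::fifelse(dm, "t1d", "none"))
  ev <- rep("", length(ids))
  ev[fl$widenet] <- "widenet"
  ev[dm] <- paste0(ev[dm], ";dm_codes")
  ev[t2d] <- paste0(ev[t2d], ";t2d_rule")
  data.table::data.table(patient_id = ids, label = label, evidence = ev)
}
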