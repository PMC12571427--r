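## Threshold and code/medication constants for the two computable phenotypes.

## Non-insulin antidiabetic ingredients recognised by CP 1 ("other
## prescriptions"); 29 ingredients, lowercase, deduplicated.
CP1_NONINSULIN_MEDICATIONS <- sort(c(
  "albiglutide", "alogliptin", "chlorpropamide", "dulaglutide",
  "ertugliflozin", "exenatide", "glimepiride", "glipizide", "glyburide",
  "liraglutide", "lixisenatide", "pramlintide", "rosiglitazone",
  "semaglutide", "sitagliptin", "tolazamide", "tolbutamide", "acarbose",
  "canagliflozin", "dapagliflozin", "empagliflozin", "gliclazide",
  "linagliptin", "miglitol", "nateglinide", "pioglitazone", "repaglinide",
  "saxagliptin", "tirzepatide"
))

## Wide-net diabetes-related medications recognised by CP 2 (16 entries;
## includes insulin and metformin plus two class names kept verbatim).
CP2_WIDENET_MEDICATIONS <- sort(c(
  "exenatide", "gliclazide", "glimepiride", "glipizide", "glyburide",
  "insulin", "meglitinide", "metformin", "nateglinide", "pioglitazone",
  "pramlintide", "repaglinide", "rosiglitazone", "sitagliptin",
  "sulfonylurea", "thiazolidinediones"
))

#' Decision constants for computable phenotype 1
#'
#' CP 1 detects diabetes from abnormal laboratory results, diagnosis codes
#' or antidiabetic prescriptions, then reclassifies detected cases as type 1
#' diabetes (T1D) when T1D-specific markers are present; remaining cases are
#' type 2 (T2D).
#'
#' @param lab_occasions_mode How the "2 or more occasions within a 2-year
#'   period" qualifier is applied to the three laboratory criteria:
#'   `"pooled"` (default; any mix of abnormal HbA1c / fasting glucose /
#'   random glucose on two distinct dates) or `"per_criterion"` (each
#'   criterion must individually reach two dates).
#' @return A list of class `cp1_criteria` holding thresholds (HbA1c 6.5%,
#'   fasting glucose 126 mg/dL, random glucose 200 mg/dL, C-peptide
#'   0.8 ng/mL), code patterns, the non-insulin medication list and the
#'   T1D:T2D code-ratio threshold (0.5).
#' @export
cp1_criteria <- function(lab_occasions_mode = c("pooled", "per_criterion")) {
  structure(list(
    hba1c_threshold = 6.5,
    fasting_glucose_threshold = 126,
    random_glucose_threshold = 200,
    min_occasions = 2L,
    occasion_window_years = 2L,
    dx_patterns_icd9 = "250.x",
    dx_patterns_icd10 = c("E10.x", "E11.x", "E14.x"),
    noninsulin_medications = CP1_NONINSULIN_MEDICATIONS,
    c_peptide_t1d_threshold = 0.8,
    t1d_ratio_threshold = 0.5,
    lab_occasions_mode = match.arg(lab_occasions_mode)
  ), class = "cp1_criteria")
}

#' Decision constants for computable phenotype 2
#'
#' CP 2 first casts a wide net (any diabetes-related lab, diagnosis code or
#' medication event), then confirms diabetes mellitus (DM) cases from
#' diagnosis codes only, and finally classifies confirmed cases as T2D.
#'
#' @param t2d_rule_mode T2D classification rule for confirmed DM cases:
#'   `"or_printed"` (default) applies the three clauses as printed -- code
#'   ratio at most 0.5, OR any antidiabetic medication besides insulin or
#'   metformin, OR no glucagon medication event; `"ratio_only"` uses the
#'   ratio clause alone.
#' @param include_e09 Add `E09.x` (drug-induced diabetes) to the DM code
#'   patterns (off by default).
#' @param min_encounters Encounters required in the 3-year window for
#'   denominator eligibility (default 1; 2 is the stricter variant).
#' @return A list of class `cp2_criteria`.
#' @export
cp2_criteria <- function(t2d_rule_mode = c("or_printed", "ratio_only"),
                         include_e09 = FALSE, min_encounters = 1L) {
  dm_icd10 <- c("E08.x", "E10.x", "E11.x", "E13.x")
  if (isTRUE(include_e09)) dm_icd10 <- sort(c(dm_icd10, "E09.x"))
  structure(list(
    hba1c_threshold = 6.5,
    fasting_glucose_threshold = 126,
    random_glucose_threshold = 200,
    widenet_medications = CP2_WIDENET_MEDICATIONS,
    dm_dx_patterns_icd9 = c("250.x0", "250.x2"),
    dm_dx_patterns_icd10 = dm_icd10,
    t1d_ratio_threshold = 0.5,
    t2d_rule_mode = match.arg(t2d_rule_mode),
    min_encounters = as.integer(min_encounters),
    lookback_years = 3L
  ), class = "cp2_criteria")
}

## ICD-9 fifth-digit type conventions: x0/x2 are type 2, x1/x3 are type 1.
ICD9_T1D_PATTERNS <- c("250.x1", "250.x3")
ICD9_T2D_PATTERNS <- c("250.x0", "250.x2")
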