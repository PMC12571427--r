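# Independent per-patient oracles for both phenotypes, written naively from
# the rule text in plain base R.  They deliberately share no code with the
# package's vectorized classifiers.

ORACLE_CP1_ORALS <- c(
  "albiglutide", "alogliptin", "chlorpropamide", "dulaglutide",
  "ertugliflozin", "exenatide", "glimepiride", "glipizide", "glyburide",
  "liraglutide", "lixisenatide", "pramlintide", "rosiglitazone",
  "semaglutide", "sitagliptin", "tolazamide", "tolbutamide", "acarbose",
  "canagliflozin", "dapagliflozin", "empagliflozin", "gliclazide",
  "linagliptin", "miglitol", "nateglinide", "pioglitazone", "repaglinide",
  "saxagliptin", "tirzepatide")

ORACLE_CP2_MEDS <- c(
  "exenatide", "gliclazide", "glimepiride", "glipizide", "glyburide",
  "insulin", "meglitinide", "metformin", "nateglinide", "pioglitazone",
  "pramlintide", "repaglinide", "rosiglitazone", "sitagliptin",
  "sulfonylurea", "thiazolidinediones")

oracle_window <- function(tbl, win) tbl[tbl$date >= win[1] & tbl$date <= win[2], , drop = FALSE]

# is an ICD code (already dotless) a type 1 / type 2 diabetes code?
oracle_is_t1 <- function(sys, code) {
  (sys == "ICD10" & startsWith(code, "E10")) |
    (sys == "ICD9" & startsWith(code, "250") & nchar(code) == 5 &
       substr(code, 5, 5) %in% c("1", "3"))
}
oracle_is_t2 <- function(sys, code) {
  (sys == "ICD10" & startsWith(code, "E11")) |
    (sys == "ICD9" & startsWith(code, "250") & nchar(code) == 5 &
       substr(code, 5, 5) %in% c("0", "2"))
}

# CP 1: diabetes if (>=2 abnormal-lab dates) or (>=2 diabetes-code dates) or
# (insulin rx outside pregnancy) or (any listed non-insulin rx);
# then T1D if C-peptide<0.8 / autoantibody+ / acetone strips /
# ratio>0.5 & glucagon / ratio>0.5 & never oral.  Else T2D.
oracle_cp1_label <- function(pv, win) {
  labs <- oracle_window(as.data.frame(pv$labs), win)
  v <- suppressWarnings(as.numeric(labs$value))
  abnormal <- (labs$analyte == "hba1c" & v >= 6.5) |
    (labs$analyte == "fasting_glucose" & v >= 126) |
    (labs$analyte == "random_glucose" & v >= 200)
  lab_crit <- length(unique(labs$date[abnormal])) >= 2

  dx <- oracle_window(as.data.frame(pv$diagnoses), win)
  dia_code <- (dx$code_system == "ICD9" & startsWith(dx$code, "250")) |
    (dx$code_system == "ICD10" &
       (startsWith(dx$code, "E10") | startsWith(dx$code, "E11") |
          startsWith(dx$code, "E14")))
  dx_crit <- length(unique(dx$date[dia_code])) >= 2

  rx <- oracle_window(as.data.frame(pv$medications), win)
  rx <- rx[rx$event_type == "prescribed", , drop = FALSE]
  preg <- as.data.frame(pv$pregnancies)
  ins_dates <- rx$date[rx$ingredient == "insulin"]
  outside <- vapply(ins_dates, function(d) {
    !any(preg$start_date <= d & d <= preg$end_date)
  }, logical(1))
  ins_crit <- any(outside)
  oral_crit <- any(rx$ingredient %in% ORACLE_CP1_ORALS)

  if (!(lab_crit || dx_crit || ins_crit || oral_crit)) return("none")

  cpep <- labs$analyte == "c_peptide" & !is.na(v) & v < 0.8
  autoab <- labs$analyte == "diabetes_autoantibody" & labs$value == "positive"
  strips <- any(rx$ingredient == "urine acetone test strips")
  glucagon <- any(rx$ingredient == "glucagon")
  t1n <- sum(oracle_is_t1(dx$code_system, dx$code))
  t2n <- sum(oracle_is_t2(dx$code_system, dx$code))
  ratio_gt <- if (t2n > 0) (t1n / t2n) > 0.5 else t1n > 0
  t1d <- any(cpep) || any(autoab) || strips ||
    (ratio_gt && glucagon) || (ratio_gt && !oral_crit)
  if (t1d) "t1d" else "t2d"
}

# CP 2: wide net (any abnormal lab / any DM-related code / any listed med
# event), then DM case iff >=1 DM code, then T2D per mode.
oracle_cp2_label <- function(pv, win, mode = "or_printed") {
  labs <- oracle_window(as.data.frame(pv$labs), win)
  v <- suppressWarnings(as.numeric(labs$value))
  lab_any <- any((labs$analyte == "hba1c" & v >= 6.5) |
                   (labs$analyte == "fasting_glucose" & v >= 126) |
                   (labs$analyte == "random_glucose" & v >= 200))

  dx <- oracle_window(as.data.frame(pv$diagnoses), win)
  dm_code <- (dx$code_system == "ICD10" &
                (startsWith(dx$code, "E08") | startsWith(dx$code, "E10") |
                   startsWith(dx$code, "E11") | startsWith(dx$code, "E13"))) |
    (dx$code_system == "ICD9" & startsWith(dx$code, "250") &
       nchar(dx$code) == 5 & substr(dx$code, 5, 5) %in% c("0", "1", "2", "3"))

  meds <- oracle_window(as.data.frame(pv$medications), win)
  med_any <- any(meds$ingredient %in% ORACLE_CP2_MEDS)

  if (!(lab_any || any(dm_code) || med_any)) return("none")
  dm_n <- sum(dm_code)
  if (dm_n == 0) return("none")
  t1_n <- sum(dm_code & oracle_is_t1(dx$code_system, dx$code))
  ratio_ok <- (t1_n / dm_n) <= 0.5
  besides <- any(meds$ingredient %in% setdiff(ORACLE_CP2_MEDS, c("insulin", "metformin")))
  no_glucagon <- !any(meds$ingredient == "glucagon")
  t2d <- if (mode == "ratio_only") ratio_ok else (ratio_ok || besides || no_glucagon)
  if (t2d) "t2d" else "t1d"
}

oracle_labels <- function(bundle, year, cp = c("cp1", "cp2"),
                          mode = "or_printed") {
  cp <- match.arg(cp)
  win <- calendar_window(year, if (cp == "cp1") 2L else 3L)
  ids <- bundle$patients$patient_id
  vapply(ids, function(id) {
    pv <- lapply(bundle[c("patients", "encounters", "diagnoses", "labs",
                          "medications", "pregnancies")],
                 function(tb) tb[tb$patient_id == id, ])
    if (cp == "cp1") oracle_cp1_label(pv, win) else oracle_cp2_label(pv, win, mode)
  }, character(1), USE.NAMES = FALSE)
}
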