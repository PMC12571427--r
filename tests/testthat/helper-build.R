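# Compact fixture builders used across the unit tests.

d <- function(x) as.Date(x)

# One-patient bundle from record sketches.
# labs: list(c(date, analyte, value)); dx: list(c(date, system, code));
# meds: list(c(date, ingredient[, event_type])); enc: list(c(date, system));
# preg: list(c(start, end))
mk_bundle <- function(id = "p1", birth = "1990-06-15", sex = "female",
                      race = "white", labs = NULL, dx = NULL, meds = NULL,
                      enc = NULL, preg = NULL, cp1_systems = NULL) {
  row_df <- function(rows, build) {
    if (is.null(rows)) return(NULL)
    do.call(rbind, lapply(rows, build))
  }
  labs_df <- row_df(labs, function(r) data.frame(
    patient_id = id, date = d(r[1]), analyte = r[2], value = r[3],
    units = if (r[2] == "hba1c") "%" else "mg/dL"))
  dx_df <- row_df(dx, function(r) data.frame(
    patient_id = id, date = d(r[1]), code_system = r[2], code = r[3],
    setting = "outpatient"))
  meds_df <- row_df(meds, function(r) data.frame(
    patient_id = id, date = d(r[1]), ingredient = r[2],
    event_type = if (length(r) > 2) r[3] else "prescribed"))
  enc_df <- row_df(enc, function(r) data.frame(
    patient_id = id, date = d(r[1]),
    system_id = if (length(r) > 1) r[2] else "sys_a", setting = "outpatient"))
  preg_df <- row_df(preg, function(r) data.frame(
    patient_id = id, start_date = d(r[1]), end_date = d(r[2])))
  ehr_bundle(
    patients = data.frame(patient_id = id, birth_date = d(birth),
                          sex = sex, race_ethnicity = race),
    encounters = enc_df, diagnoses = dx_df, labs = labs_df,
    medications = meds_df, pregnancies = preg_df,
    cp1_systems = if (is.null(cp1_systems)) {
      if (is.null(enc_df)) character(0) else unique(enc_df$system_id)
    } else cp1_systems)
}

pv_of <- function(bundle, id = bundle$patients$patient_id[1]) {
  lapply(bundle[c("patients", "encounters", "diagnoses", "labs",
                  "medications", "pregnancies")],
         function(tb) tb[tb$patient_id == id, ])
}

# Chaotic multi-patient bundle: random mixes of codes (both systems, typed,
# untyped and irrelevant), threshold-straddling labs and medications
# including glucagon / acetone strips, to stress the classifiers against
# the oracles well beyond what the structured generator produces.
random_bundle <- function(n = 200, seed = 1, year = 2022) {
  set.seed(seed)
  ids <- sprintf("r%04d", seq_len(n))
  win <- calendar_window(year, 3L)
  rdate <- function(m) win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, m,
                                           replace = TRUE) - 1L
  codes <- data.frame(
    code_system = c(rep("ICD10", 8), rep("ICD9", 6)),
    code = c("E109", "E1065", "E119", "E1122", "E149", "E089", "E139", "I10",
             "25000", "25001", "25002", "25003", "2500", "4019"))
  med_pool <- c("insulin", "metformin", "glipizide", "glucagon",
                "urine acetone test strips", "empagliflozin", "lisinopril",
                "semaglutide", "sulfonylurea")
  lab_pool <- data.frame(
    analyte = c("hba1c", "hba1c", "fasting_glucose", "fasting_glucose",
                "random_glucose", "random_glucose", "c_peptide", "c_peptide",
                "diabetes_autoantibody", "diabetes_autoantibody"),
    value = c("6.4", "6.5", "125", "126", "199", "200", "0.79", "0.8",
              "positive", "negative"))
  one <- function(pool, m) pool[sample.int(nrow(pool), m, replace = TRUE), ]

  dx <- do.call(rbind, lapply(ids, function(id) {
    m <- rpois(1, 2)
    if (m == 0) return(NULL)
    cbind(data.frame(patient_id = id, date = rdate(m)), one(codes, m),
          data.frame(setting = sample(c("inpatient", "outpatient"), m, TRUE)))
  }))
  labs <- do.call(rbind, lapply(ids, function(id) {
    m <- rpois(1, 2)
    if (m == 0) return(NULL)
    cbind(data.frame(patient_id = id, date = rdate(m)), one(lab_pool, m),
          data.frame(units = ""))
  }))
  meds <- do.call(rbind, lapply(ids, function(id) {
    m <- rpois(1, 1.5)
    if (m == 0) return(NULL)
    data.frame(patient_id = id, date = rdate(m),
               ingredient = sample(med_pool, m, TRUE),
               event_type = sample(c("prescribed", "dispensed", "administered"),
                                   m, TRUE, prob = c(0.6, 0.2, 0.2)))
  }))
  preg_ids <- sample(ids, n %/% 10)
  preg_start <- rdate(length(preg_ids))
  ehr_bundle(
    patients = data.frame(
      patient_id = ids,
      birth_date = d("1985-01-01") + sample.int(7000, n, replace = TRUE),
      sex = sample(c("female", "male"), n, TRUE),
      race_ethnicity = sample(c("white", "african_american", "hispanic",
                                "asian", "other"), n, TRUE)),
    encounters = data.frame(patient_id = ids, date = rdate(n),
                            system_id = sample(c("sys_a", "sys_x"), n, TRUE),
                            setting = "outpatient"),
    diagnoses = dx, labs = labs, medications = meds,
    pregnancies = data.frame(patient_id = preg_ids, start_date = preg_start,
                             end_date = preg_start + 200),
    cp1_systems = "sys_a")
}
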