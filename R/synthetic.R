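## Synthetic EHR generator: a stated world with known true disease labels
## (none / t1d / t2d) per demographic stratum, a patient-level two-system
## catchment, and per-domain observation (capture) processes.

AGE_GROUPS <- c("18-24", "25-34", "35-44")
AGE_BOUNDS <- list(`18-24` = c(18L, 24L), `25-34` = c(25L, 34L),
                   `35-44` = c(35L, 44L))

default_stratum_mix <- function() {
  sex_p <- c(female = 0.553, male = 0.447)
  age_p <- c(`18-24` = 0.253, `25-34` = 0.390, `35-44` = 0.357)
  race_p <- c(african_american = 0.153, asian = 0.037, hispanic = 0.096,
              white = 0.590, other = 0.124)
  mix <- data.table::CJ(sex = names(sex_p), age_group = names(age_p),
                        race_ethnicity = names(race_p))
  mix[, prob := sex_p[sex] * age_p[age_group] * race_p[race_ethnicity]]
  mix[]
}

#' Simulation configuration for the synthetic EHR generator
#'
#' The defaults describe a fixed "stated world": a young-adult (18-44)
#' population with age-dependent true T2D prevalence, a patient-level
#' two-system catchment containing roughly 44% of patients, imperfect
#' capture of labs, medications and diagnoses, and occasional type
#' miscoding of diabetes diagnosis codes.
#'
#' @param n_patients Number of patients to simulate.
#' @param prevalence_year Year whose prevalence is measured (default 2022).
#' @param stratum_mix Data frame with columns `sex`, `age_group`,
#'   `race_ethnicity`, `prob` summing to 1.
#' @param true_t2d_prev Named numeric vector of true T2D probability by age
#'   group (or a single number applied to all groups).
#' @param true_t1d_prev True T1D probability (scalar or named by age group).
#' @param encounter_rate Expected encounters per patient per year.
#' @param lab_capture_prob,med_capture_prob,dx_capture_prob Probability that
#'   a clinically true lab / medication / diagnosis event is recorded.
#' @param type_miscode_prob Probability an individual diabetes diagnosis
#'   occurrence carries the wrong type (E10 vs E11; ICD-9 fifth digit).
#' @param pregnancy_prob Per-female probability of one pregnancy interval
#'   inside the observation window.
#' @param gestational_insulin_prob Among pregnant women, probability of an
#'   insulin prescription dated inside the pregnancy interval.
#' @param unspecified_code_prob Probability a diabetes code occurrence uses
#'   an unspecified-type code (E14.x for CP 1, E08.x for CP 2) instead of a
#'   typed code; 0 by default because the two phenotypes treat these codes
#'   asymmetrically.
#' @param catchment_fraction Probability that a patient's care (all their
#'   encounters) occurs inside CP 1's two-system catchment.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10000L,
                       prevalence_year = 2022L,
                       stratum_mix = default_stratum_mix(),
                       true_t2d_prev = c(`18-24` = 0.010, `25-34` = 0.030,
                                         `35-44` = 0.060),
                       true_t1d_prev = 0.005,
                       encounter_rate = 2,
                       lab_capture_prob = 0.9,
                       med_capture_prob = 0.7,
                       dx_capture_prob = 0.9,
                       type_miscode_prob = 0.05,
                       pregnancy_prob = 0.10,
                       gestational_insulin_prob = 0.30,
                       unspecified_code_prob = 0,
                       catchment_fraction = 0.44,
                       seed = 20220101L) {
  expand_by_age <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(as.numeric(x), 3L), AGE_GROUPS)
    }
    if (!all(AGE_GROUPS %in% names(x))) {
      stop(what, " must be a scalar or named by age group")
    }
    x[AGE_GROUPS]
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    prevalence_year = as.integer(prevalence_year),
    stratum_mix = data.table::as.data.table(stratum_mix),
    true_t2d_prev = expand_by_age(true_t2d_prev, "true_t2d_prev"),
    true_t1d_prev = expand_by_age(true_t1d_prev, "true_t1d_prev"),
    encounter_rate = as.numeric(encounter_rate),
    lab_capture_prob = as.numeric(lab_capture_prob),
    med_capture_prob = as.numeric(med_capture_prob),
    dx_capture_prob = as.numeric(dx_capture_prob),
    type_miscode_prob = as.numeric(type_miscode_prob),
    pregnancy_prob = as.numeric(pregnancy_prob),
    gestational_insulin_prob = as.numeric(gestational_insulin_prob),
    unspecified_code_prob = as.numeric(unspecified_code_prob),
    catchment_fraction = as.numeric(catchment_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L) stop("n_patients must be >= 0")
  probs <- c(cfg$true_t2d_prev, cfg$true_t1d_prev, cfg$lab_capture_prob,
             cfg$med_capture_prob, cfg$dx_capture_prob, cfg$type_miscode_prob,
             cfg$pregnancy_prob, cfg$gestational_insulin_prob,
             cfg$unspecified_code_prob, cfg$catchment_fraction)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (any(cfg$true_t2d_prev + cfg$true_t1d_prev > 1)) {
    stop("true_t2d_prev + true_t1d_prev must not exceed 1")
  }
  if (cfg$encounter_rate < 0) stop("encounter_rate must be >= 0")
  mix <- cfg$stratum_mix
  need <- c("sex", "age_group", "race_ethnicity", "prob")
  if (!all(need %in% names(mix))) stop("stratum_mix needs columns ", paste(need, collapse = ", "))
  if (abs(sum(mix$prob) - 1) > 1e-9) stop("stratum_mix probabilities must sum to 1")
  if (any(mix$prob < 0)) stop("stratum_mix probabilities must be non-negative")
  invisible(cfg)
}

## Sample `n[i]` distinct day offsets in [0, n_days) for each group i.
## Returns a data.table(idx, offset) ordered by group.
distinct_day_offsets <- function(n, n_days) {
  keep <- which(n > 0L)
  if (!length(keep)) {
    return(data.table::data.table(idx = integer(0), offset = integer(0)))
  }
  dt <- data.table::data.table(idx = keep, n_events = n[keep])
  dt[, .(offset = sample.int(n_days, n_events) - 1L), by = idx]
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic EHR population with known truth labels
#'
#' Clinical truth is generated first (who has T1D/T2D, and the full stream
#' of true clinical events), then each lab, diagnosis and medication event
#' is independently thinned by its capture probability.  Because every
#' random draw happens before thinning, two configurations differing only
#' in capture probabilities share the same underlying event stream (common
#' random numbers), and lowering a capture probability can only remove
#' records.
#'
#' Diabetic patients receive their clinical events inside the two calendar
#' years ending with `prevalence_year` (the shorter of the two phenotype
#' windows); encounters span the full three-year window.  Event dates
#' within one patient and event family are distinct calendar dates.
#'
#' @param config A [sim_config()].
#' @return `list(bundle = ehr_bundle, truth = data.table)` where `truth`
#'   has columns `patient_id`, `true_label`, `sex`, `age_group`,
#'   `race_ethnicity`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  validate_sim_config(config)
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  n <- cfg$n_patients
  year <- cfg$prevalence_year
  win3 <- calendar_window(year, 3L)
  win2 <- calendar_window(year, 2L)
  n_days3 <- as.integer(win3[2] - win3[1]) + 1L
  n_days2 <- as.integer(win2[2] - win2[1]) + 1L

  if (n == 0L) {
    bundle <- ehr_bundle()
    truth <- data.table::data.table(patient_id = character(0),
                                    true_label = character(0),
                                    sex = character(0), age_group = character(0),
                                    race_ethnicity = character(0))
    return(list(bundle = bundle, truth = truth))
  }

  mix <- cfg$stratum_mix
  stratum_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$prob)
  pts <- data.table::data.table(
    patient_id = sprintf("p%06d", seq_len(n)),
    sex = mix$sex[stratum_idx],
    age_group = mix$age_group[stratum_idx],
    race_ethnicity = mix$race_ethnicity[stratum_idx]
  )
  ## birth year pins the completed age on Dec 31 of the prevalence year
  lo <- vapply(AGE_BOUNDS[pts$age_group], `[`, integer(1), 1L)
  hi <- vapply(AGE_BOUNDS[pts$age_group], `[`, integer(1), 2L)
  age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  birth_year <- year - age
  day_in_year <- floor(stats::runif(n) * 365)
  pts[, birth_date := as.Date(sprintf("%d-01-01", birth_year)) + day_in_year]

  p_t2d <- cfg$true_t2d_prev[pts$age_group]
  p_t1d <- cfg$true_t1d_prev[pts$age_group]
  u <- stats::runif(n)
  pts[, true_label := data.table::fifelse(u < p_t2d, "t2d",
                        data.table::fifelse(u < p_t2d + p_t1d, "t1d", "none"))]
  pts[, in_catchment := stats::runif(n) < cfg$catchment_fraction]

  ## --- encounters: full 3-year window, any system -----------------------
  n_enc <- stats::rpois(n, cfg$encounter_rate * 3)
  enc_pt <- rep(seq_len(n), n_enc)
  encounters <- data.table::data.table(
    patient_id = pts$patient_id[enc_pt],
    date = win3[1] + floor(stats::runif(length(enc_pt)) * n_days3),
    system_id = data.table::fifelse(
      pts$in_catchment[enc_pt],
      c("sys_a", "sys_b")[1L + (stats::runif(length(enc_pt)) < 0.4)],
      c("sys_c", "sys_d")[1L + (stats::runif(length(enc_pt)) < 0.3)]),
    setting = sample(SETTING_LEVELS, length(enc_pt), replace = TRUE,
                     prob = c(0.1, 0.8, 0.1))
  )

  ## --- pregnancies (females), fully inside the 3-year window ------------
  is_f <- pts$sex == "female"
  preg_u <- stats::runif(n)
  pregnant <- is_f & preg_u < cfg$pregnancy_prob
  preg_start <- win3[1] + floor(stats::runif(n) * (n_days3 - 270L))
  pregnancies <- data.table::data.table(
    patient_id = pts$patient_id[pregnant],
    start_date = preg_start[pregnant],
    end_date = preg_start[pregnant] + 269L
  )
  gest_u <- stats::runif(n)
  gest_ins <- pregnant & pts$true_label == "none" &
    gest_u < cfg$gestational_insulin_prob

  ## --- true clinical event streams (diabetics; 2-year window) -----------
  t2d <- which(pts$true_label == "t2d")
  t1d <- which(pts$true_label == "t1d")
  none <- which(pts$true_label == "none")

  n_dx  <- integer(n); n_lab <- integer(n)
  n_dx[t2d]  <- 1L + stats::rpois(length(t2d), 1)
  n_dx[t1d]  <- 2L + stats::rpois(length(t1d), 1)
  n_lab[t2d] <- 2L + stats::rpois(length(t2d), 1)
  n_lab[t1d] <- 2L + stats::rpois(length(t1d), 1)
  n_lab[none] <- stats::rpois(length(none), 1)

  ## diagnosis occurrences with type-aware codes and miscoding noise
  dx_off <- distinct_day_offsets(n_dx, n_days2)
  dx <- data.table::data.table(idx = dx_off$idx,
                               date = win2[1] + dx_off$offset)
  dx[, true_type := pts$true_label[idx]]
  m <- nrow(dx)
  if (m) {
    icd10 <- stats::runif(m) < 0.75
    suffix_u <- stats::runif(m)
    unspec_u <- stats::runif(m)
    flip <- stats::runif(m) < cfg$type_miscode_prob
    coded_type <- data.table::fifelse(flip,
                                      data.table::fifelse(dx$true_type == "t2d", "t1d", "t2d"),
                                      dx$true_type)
    suffix10 <- data.table::fifelse(suffix_u < 0.7, "9", "65")
    code10 <- paste0(data.table::fifelse(coded_type == "t2d", "E11", "E10"), suffix10)
    code9 <- data.table::fifelse(coded_type == "t2d",
                                 data.table::fifelse(suffix_u < 0.6, "25000", "25002"),
                                 data.table::fifelse(suffix_u < 0.6, "25001", "25003"))
    code <- data.table::fifelse(icd10, code10, code9)
    unspec <- icd10 & unspec_u < cfg$unspecified_code_prob
    code[unspec] <- c("E149", "E089")[1L + (suffix_u[unspec] < 0.5)]
    dx[, `:=`(code_system = data.table::fifelse(icd10, "ICD10", "ICD9"),
              code = code,
              setting = c("outpatient", "inpatient")[1L + (stats::runif(m) < 0.15)],
              capture_u = stats::runif(m))]
  } else {
    dx[, `:=`(code_system = character(0), code = character(0),
              setting = character(0), capture_u = numeric(0))]
  }

  ## laboratory results: abnormal for diabetics, normal for non-diabetics
  lab_off <- distinct_day_offsets(n_lab, n_days2)
  labs <- data.table::data.table(idx = lab_off$idx,
                                 date = win2[1] + lab_off$offset)
  labs[, diabetic := pts$true_label[idx] != "none"]
  ## non-diabetic routine labs may fall anywhere in the 3-year window
  labs[diabetic == FALSE,
       date := win3[1] + floor(stats::runif(.N) * n_days3)]
  m <- nrow(labs)
  if (m) {
    a_u <- stats::runif(m)
    analyte <- data.table::fifelse(a_u < 0.6, "hba1c",
                 data.table::fifelse(a_u < 0.8, "fasting_glucose", "random_glucose"))
    v_u <- stats::runif(m)
    value <- numeric(m)
    dia <- labs$diabetic
    value[analyte == "hba1c" & dia] <- 6.6 + v_u[analyte == "hba1c" & dia] * 4.4
    value[analyte == "hba1c" & !dia] <- 4.5 + v_u[analyte == "hba1c" & !dia] * 1.5
    value[analyte == "fasting_glucose" & dia] <- 130 + v_u[analyte == "fasting_glucose" & dia] * 120
    value[analyte == "fasting_glucose" & !dia] <- 75 + v_u[analyte == "fasting_glucose" & !dia] * 45
    value[analyte == "random_glucose" & dia] <- 210 + v_u[analyte == "random_glucose" & dia] * 140
    value[analyte == "random_glucose" & !dia] <- 80 + v_u[analyte == "random_glucose" & !dia] * 100
    labs[, `:=`(analyte = analyte,
                value = as.character(round(value, 1)),
                units = data.table::fifelse(analyte == "hba1c", "%", "mg/dL"),
                capture_u = stats::runif(m))]
  } else {
    labs[, `:=`(analyte = character(0), value = character(0),
                units = character(0), capture_u = numeric(0))]
  }

  ## T1D-specific labs: C-peptide below threshold and/or positive
  ## autoantibody, each with probability 0.5
  t1d_cpep <- t1d[stats::runif(length(t1d)) < 0.5]
  t1d_ab   <- t1d[stats::runif(length(t1d)) < 0.5]
  extra_labs <- data.table::rbindlist(list(
    data.table::data.table(
      idx = t1d_cpep,
      date = win2[1] + floor(stats::runif(length(t1d_cpep)) * n_days2),
      diabetic = TRUE, analyte = "c_peptide",
      value = as.character(round(0.2 + stats::runif(length(t1d_cpep)) * 0.5, 2)),
      units = "ng/mL", capture_u = stats::runif(length(t1d_cpep))),
    data.table::data.table(
      idx = t1d_ab,
      date = win2[1] + floor(stats::runif(length(t1d_ab)) * n_days2),
      diabetic = TRUE, analyte = "diabetes_autoantibody",
      value = "positive", units = "", capture_u = stats::runif(length(t1d_ab)))
  ))
  labs <- data.table::rbindlist(list(labs, extra_labs), use.names = TRUE)

  ## medications: T2D -> metformin plus a listed oral agent; T1D -> insulin
  ## and glucagon (and sometimes acetone test strips); gestational insulin
  n_med <- integer(n)
  n_med[t2d] <- 2L + stats::rpois(length(t2d), 1)
  med_off <- distinct_day_offsets(n_med, n_days2)
  meds_t2d <- data.table::data.table(idx = med_off$idx,
                                     date = win2[1] + med_off$offset)
  m <- nrow(meds_t2d)
  if (m) {
    pool <- c("metformin", "metformin", "glipizide", "sitagliptin",
              "glimepiride", "empagliflozin")
    meds_t2d[, `:=`(ingredient = pool[1L + floor(stats::runif(m) * length(pool))],
                    event_type = c("prescribed", "dispensed")[1L + (stats::runif(m) < 0.25)],
                    capture_u = stats::runif(m))]
    ## CP 1 detection reads prescriptions only: guarantee the first listed
    ## medication event of each T2D patient is a prescription
    meds_t2d[meds_t2d[, .I[1], by = idx]$V1, event_type := "prescribed"]
  } else {
    meds_t2d[, `:=`(ingredient = character(0), event_type = character(0),
                    capture_u = numeric(0))]
  }

  n_ins <- integer(n); n_glu <- integer(n)
  n_ins[t1d] <- 1L + stats::rpois(length(t1d), 1)
  n_glu[t1d] <- 2L + stats::rpois(length(t1d), 0.5)
  ins_off <- distinct_day_offsets(n_ins, n_days2)
  meds_ins <- data.table::data.table(idx = ins_off$idx,
                                     date = win2[1] + ins_off$offset,
                                     ingredient = "insulin")
  glu_off <- distinct_day_offsets(n_glu, n_days2)
  meds_glu <- data.table::data.table(idx = glu_off$idx,
                                     date = win2[1] + glu_off$offset,
                                     ingredient = "glucagon")
  t1d_strips <- t1d[stats::runif(length(t1d)) < 0.3]
  meds_strips <- data.table::data.table(
    idx = t1d_strips,
    date = win2[1] + floor(stats::runif(length(t1d_strips)) * n_days2),
    ingredient = "urine acetone test strips")
  meds_gest <- data.table::data.table(
    idx = which(gest_ins),
    date = preg_start[gest_ins] + 140L,
    ingredient = "insulin")
  meds_t1d <- data.table::rbindlist(list(meds_ins, meds_glu, meds_strips, meds_gest))
  m <- nrow(meds_t1d)
  meds_t1d[, `:=`(event_type = "prescribed", capture_u = stats::runif(m))]
  meds <- data.table::rbindlist(list(
    meds_t2d[, .(idx, date, ingredient, event_type, capture_u)],
    meds_t1d[, .(idx, date, ingredient, event_type, capture_u)]))

  ## --- observation process: thin truth events by capture probability ----
  dx <- dx[capture_u <= cfg$dx_capture_prob]
  labs <- labs[capture_u <= cfg$lab_capture_prob]
  meds <- meds[capture_u <= cfg$med_capture_prob]

  diagnoses <- data.table::data.table(
    patient_id = pts$patient_id[dx$idx], date = dx$date,
    code_system = dx$code_system, code = dx$code, setting = dx$setting)
  labs_tbl <- data.table::data.table(
    patient_id = pts$patient_id[labs$idx], date = labs$date,
    analyte = labs$analyte, value = labs$value, units = labs$units)
  meds_tbl <- data.table::data.table(
    patient_id = pts$patient_id[meds$idx], date = meds$date,
    ingredient = meds$ingredient, event_type = meds$event_type)

  data.table::setorder(diagnoses, patient_id, date, code)
  data.table::setorder(labs_tbl, patient_id, date, analyte, value)
  data.table::setorder(meds_tbl, patient_id, date, ingredient)
  data.table::setorder(encounters, patient_id, date, system_id)

  bundle <- ehr_bundle(
    patients = pts[, .(patient_id, birth_date, sex, race_ethnicity)],
    encounters = encounters, diagnoses = diagnoses, labs = labs_tbl,
    medications = meds_tbl, pregnancies = pregnancies,
    cp1_systems = intersect(c("sys_a", "sys_b"), unique(encounters$system_id)))
  truth <- pts[, .(patient_id, true_label, sex, age_group, race_ethnicity)]
  list(bundle = bundle, truth = truth)
}

#' True T2D prevalence in a stratum of the truth table
#'
#' @param truth Truth table from [generate_population()].
#' @param stratum Either `"overall"` or `c(dimension, level)`, e.g.
#'   `c("age_group", "35-44")`.
#' @return Exact fraction of T2D-true patients in the stratum.
#' @export
truth_prevalence <- function(truth, stratum = "overall") {
  truth <- data.table::as.data.table(truth)
  if (identical(stratum[1], "overall")) {
    sub <- truth
  } else {
    if (length(stratum) != 2L || !stratum[1] %in% names(truth)) {
      stop("stratum must be 'overall' or c(dimension, level)")
    }
    sub <- truth[truth[[stratum[1]]] == stratum[2], ]
  }
  if (nrow(sub) == 0L) {
    stop("empty stratum: proportion undefined for ",
         paste(stratum, collapse = "/"))
  }
  mean(sub$true_label == "t2d")
}
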