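## Denominator eligibility, demographic stratification and prevalence tables.

#' Round half-up to a fixed number of decimals
#'
#' Presentation rounding used for printed prevalence tables (0.25 -> 0.3 at
#' one decimal), as opposed to R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Completed age in years on December 31 of a reference year
#'
#' @param birth_date Date vector.
#' @param year Reference year.
#' @return Integer ages.
#' @export
age_on_dec31 <- function(birth_date, year) {
  ref <- as.Date(sprintf("%d-12-31", as.integer(year)))
  by <- as.integer(format(birth_date, "%Y"))
  had_birthday <- format(birth_date, "%m-%d") <= format(ref, "%m-%d")
  as.integer(as.integer(year) - by - !had_birthday)
}

age_group_of <- function(age) {
  data.table::fifelse(age >= 18L & age <= 24L, "18-24",
    data.table::fifelse(age >= 25L & age <= 34L, "25-34",
      data.table::fifelse(age >= 35L & age <= 44L, "35-44", NA_character_)))
}

#' Denominator-eligible patients for a computable phenotype
#'
#' CP 1's denominator contains patients aged 18-44 (completed years on
#' December 31 of the prevalence year) with at least one encounter in the
#' two calendar years ending with the prevalence year at one of the
#' `cp1_systems`.  CP 2's denominator contains patients aged 18-44 with at
#' least `min_encounters` encounters (default 1) in the three calendar
#' years ending with the prevalence year at any system.
#'
#' @param bundle An `ehr_bundle`.
#' @param cp `"cp1"` or `"cp2"`.
#' @param prevalence_year Integer year.
#' @param min_encounters Encounter requirement for CP 2 (ignored for CP 1).
#' @return Character vector of eligible patient ids.
#' @export
eligible_patients <- function(bundle, cp = c("cp1", "cp2"), prevalence_year,
                              min_encounters = 1L) {
  cp <- match.arg(cp)
  stopifnot(inherits(bundle, "ehr_bundle"))
  age <- age_on_dec31(bundle$patients$birth_date, prevalence_year)
  in_age <- age >= 18L & age <= 44L
  enc <- bundle$encounters
  if (cp == "cp1") {
    window <- calendar_window(prevalence_year, 2L)
    enc <- enc[in_window(enc$date, window) & enc$system_id %chin% bundle$cp1_systems, ]
    min_encounters <- 1L
  } else {
    window <- calendar_window(prevalence_year, 3L)
    enc <- enc[in_window(enc$date, window), ]
  }
  counts <- enc[, .N, by = patient_id]
  ok_ids <- counts$patient_id[counts$N >= min_encounters]
  bundle$patients$patient_id[in_age & bundle$patients$patient_id %chin% ok_ids]
}

#' Stratified numerator/denominator prevalence table
#'
#' Counts T2D-labelled patients among the eligible set, overall and within
#' each level of the requested demographic dimensions.  Patients with a
#' missing value on a dimension are excluded from that dimension's strata
#' but retained in the overall row.  Empty strata are dropped with a
#' warning.
#'
#' @param labels Phenotype labels (`patient_id`, `label`), e.g. from
#'   [classify_cp1()]; must cover the eligible set.
#' @param eligible Character vector of eligible patient ids.
#' @param patients Patient table (for demographics and age).
#' @param prevalence_year Year used to derive the age group.
#' @param strata Dimensions to stratify by (default age group, race, sex).
#' @return A `data.table` with columns `dimension`, `level`, `numerator`,
#'   `denominator`, `prevalence_pct` (unrounded, in percent) and
#'   `prevalence_display` (half-up rounded to one decimal).
#' @export
prevalence_table <- function(labels, eligible, patients, prevalence_year,
                             strata = c("age_group", "race_ethnicity", "sex")) {
  labels <- data.table::as.data.table(labels)
  patients <- data.table::as.data.table(patients)
  missing_lab <- setdiff(eligible, labels$patient_id)
  if (length(missing_lab)) {
    stop("labels do not cover eligible patients, e.g. ", sQuote(missing_lab[1]))
  }
  pts <- patients[patients$patient_id %chin% eligible, ]
  pts <- merge(pts, labels[, .(patient_id, label)], by = "patient_id")
  if ("birth_date" %in% names(pts)) {
    pts[, age_group := age_group_of(age_on_dec31(birth_date, prevalence_year))]
  }
  if (nrow(pts) == 0L) stop("empty denominator: no eligible patients")
  rows <- list(data.table::data.table(
    dimension = "overall", level = "overall",
    numerator = sum(pts$label == "t2d"), denominator = nrow(pts)))
  for (dim in strata) {
    if (!dim %in% names(pts)) stop("unknown stratification dimension: ", sQuote(dim))
    sub <- pts[!is.na(pts[[dim]]), ]
    counts <- sub[, .(numerator = sum(label == "t2d"), denominator = .N),
                  by = c(dim)]
    data.table::setnames(counts, dim, "level")
    counts[, dimension := dim]
    rows[[length(rows) + 1L]] <- counts[, .(dimension, level, numerator, denominator)]
  }
  out <- data.table::rbindlist(rows)
  empty <- out$denominator == 0L
  if (any(empty)) {
    warning("dropping empty stratum(s): ",
            paste(out$level[empty], collapse = ", "))
    out <- out[!empty]
  }
  out[, prevalence_pct := 100 * numerator / denominator]
  out[, prevalence_display := round_half_up(prevalence_pct, 1)]
  data.table::setorder(out, dimension, level)
  out[]
}
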