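win2 <- calendar_window(2022, 2)

test_that("diabetes detection clauses fire as specified", {
  # two abnormal HbA1c dates in window -> lab clause
  b <- mk_bundle(labs = list(c("2021-03-01", "hba1c", "7.2"),
                             c("2022-06-01", "hba1c", "7.4")))
  r <- detect_diabetes_cp1(pv_of(b), win2)
  expect_true(r$detected)
  expect_identical(r$evidence, "lab_2_occasions")

  # one abnormal random glucose only: a single occasion is not enough
  b <- mk_bundle(labs = list(c("2022-02-01", "random_glucose", "250")))
  expect_false(detect_diabetes_cp1(pv_of(b), win2)$detected)

  # abnormal dates pooled across criteria count together
  b <- mk_bundle(labs = list(c("2021-02-01", "random_glucose", "250"),
                             c("2022-02-01", "fasting_glucose", "130")))
  expect_true(detect_diabetes_cp1(pv_of(b), win2)$detected)
  crit <- cp1_criteria(lab_occasions_mode = "per_criterion")
  expect_false(detect_diabetes_cp1(pv_of(b), win2, crit)$detected)

  # same date twice is one occasion
  b <- mk_bundle(labs = list(c("2022-02-01", "hba1c", "7.0"),
                             c("2022-02-01", "fasting_glucose", "140")))
  expect_false(detect_diabetes_cp1(pv_of(b), win2)$detected)

  # codes on two distinct dates, either system
  b <- mk_bundle(dx = list(c("2021-05-01", "ICD9", "250.00"),
                           c("2022-05-01", "ICD10", "E14.9")))
  r <- detect_diabetes_cp1(pv_of(b), win2)
  expect_true(r$detected)
  expect_identical(r$evidence, "dx_2_occasions")

  # insulin inside a pregnancy interval does not count...
  b <- mk_bundle(meds = list(c("2022-05-01", "insulin")),
                 preg = list(c("2022-01-01", "2022-09-30")))
  expect_false(detect_diabetes_cp1(pv_of(b), win2)$detected)
  # ...outside it does
  b <- mk_bundle(meds = list(c("2022-11-01", "insulin")),
                 preg = list(c("2022-01-01", "2022-09-30")))
  expect_true(detect_diabetes_cp1(pv_of(b), win2)$detected)

  # one listed non-insulin prescription suffices; dispense events do not
  b <- mk_bundle(meds = list(c("2022-05-01", "glipizide")))
  expect_true(detect_diabetes_cp1(pv_of(b), win2)$detected)
  b <- mk_bundle(meds = list(c("2022-05-01", "glipizide", "dispensed")))
  expect_false(detect_diabetes_cp1(pv_of(b), win2)$detected)

  # records outside the window are invisible
  b <- mk_bundle(labs = list(c("2020-03-01", "hba1c", "7.2"),
                             c("2020-06-01", "hba1c", "7.4")))
  expect_false(detect_diabetes_cp1(pv_of(b), win2)$detected)
})

test_that("T1D exclusion markers fire as specified", {
  expect_true(detect_t1d_cp1(pv_of(mk_bundle(
    labs = list(c("2022-02-01", "c_peptide", "0.5")))), win2)$t1d)
  expect_false(detect_t1d_cp1(pv_of(mk_bundle(
    labs = list(c("2022-02-01", "c_peptide", "0.8")))), win2)$t1d)
  expect_true(detect_t1d_cp1(pv_of(mk_bundle(
    labs = list(c("2022-02-01", "diabetes_autoantibody", "positive")))), win2)$t1d)
  expect_true(detect_t1d_cp1(pv_of(mk_bundle(
    meds = list(c("2022-02-01", "urine acetone test strips")))), win2)$t1d)

  # ratio 3:1 > 0.5 with glucagon
  b <- mk_bundle(dx = list(c("2022-01-01", "ICD10", "E10.9"),
                           c("2022-02-01", "ICD10", "E10.9"),
                           c("2022-03-01", "ICD10", "E10.9"),
                           c("2022-04-01", "ICD10", "E11.9")),
                 meds = list(c("2022-05-01", "glucagon")))
  r <- detect_t1d_cp1(pv_of(b), win2)
  expect_true(r$t1d)
  expect_true("ratio_glucagon" %in% r$evidence)

  # ratio 1:3 <= 0.5, no other marker
  b <- mk_bundle(dx = list(c("2022-01-01", "ICD10", "E10.9"),
                           c("2022-02-01", "ICD10", "E11.9"),
                           c("2022-03-01", "ICD10", "E11.9"),
                           c("2022-04-01", "ICD10", "E11.9")))
  expect_false(detect_t1d_cp1(pv_of(b), win2)$t1d)

  # all-T1D record: infinite ratio passes; never prescribed an oral agent
  b <- mk_bundle(dx = list(c("2022-01-01", "ICD9", "250.01"),
                           c("2022-02-01", "ICD9", "250.01")))
  r <- detect_t1d_cp1(pv_of(b), win2)
  expect_true(r$t1d)
  expect_identical(r$evidence, "ratio_never_oral")
  # an oral prescription blocks the never-oral clause
  b2 <- mk_bundle(dx = list(c("2022-01-01", "ICD9", "250.01"),
                            c("2022-02-01", "ICD9", "250.01")),
                  meds = list(c("2022-03-01", "glipizide")))
  expect_false(detect_t1d_cp1(pv_of(b2), win2)$t1d)
  # no diabetes codes at all: the ratio clause cannot fire
  b3 <- mk_bundle(meds = list(c("2022-03-01", "glucagon")))
  expect_false(detect_t1d_cp1(pv_of(b3), win2)$t1d)
})

test_that("labels are exhaustive, exclusive, and follow 'T2D if not T1D'", {
  b <- mk_bundle(labs = list(c("2021-03-01", "hba1c", "7.2"),
                             c("2022-06-01", "hba1c", "7.4")))
  expect_identical(classify_cp1(b, 2022)$label, "t2d")
  b <- mk_bundle()
  expect_identical(classify_cp1(b, 2022)$label, "none")
  b <- mk_bundle(labs = list(c("2021-03-01", "hba1c", "7.2"),
                             c("2022-06-01", "hba1c", "7.4"),
                             c("2022-06-01", "c_peptide", "0.4")))
  expect_identical(classify_cp1(b, 2022)$label, "t1d")

  g <- generate_population(sim_config(n_patients = 1500, seed = 3L,
                                      type_miscode_prob = 0.2))
  lab <- classify_cp1(g$bundle, 2022)
  expect_setequal(lab$patient_id, g$bundle$patients$patient_id)
  expect_true(all(lab$label %in% c("none", "t1d", "t2d")))
  expect_identical(lab$evidence == "", lab$label == "none")
})

test_that("monotonicity: extra oral medication keeps detection; removing T1D markers yields T2D", {
  base_labs <- list(c("2021-03-01", "hba1c", "7.2"),
                    c("2022-06-01", "hba1c", "7.4"))
  b <- mk_bundle(labs = base_labs)
  expect_identical(classify_cp1(b, 2022)$label, "t2d")
  b_plus <- mk_bundle(labs = base_labs,
                      meds = list(c("2022-07-01", "empagliflozin")))
  expect_identical(classify_cp1(b_plus, 2022)$label, "t2d")

  b_t1d <- mk_bundle(labs = c(base_labs, list(c("2022-06-01", "c_peptide", "0.4"),
                                              c("2022-06-02", "diabetes_autoantibody", "positive"))),
                     meds = list(c("2022-02-01", "urine acetone test strips")))
  expect_identical(classify_cp1(b_t1d, 2022)$label, "t1d")
  expect_identical(classify_cp1(mk_bundle(labs = base_labs), 2022)$label, "t2d")
})

test_that("classifier agrees label-for-label with the plain-language oracle", {
  g <- generate_population(sim_config(n_patients = 600, seed = 42L,
                                      type_miscode_prob = 0.15,
                                      lab_capture_prob = 0.6,
                                      med_capture_prob = 0.5,
                                      dx_capture_prob = 0.6))
  got <- classify_cp1(g$bundle, 2022)
  expect_identical(got$label, oracle_labels(g$bundle, 2022, "cp1"))

  rb <- random_bundle(n = 300, seed = 8)
  got <- classify_cp1(rb, 2022)
  expect_identical(got$label, oracle_labels(rb, 2022, "cp1"))
})
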