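test_that("invalid configurations are rejected before generation", {
  expect_error(sim_config(n_patients = -1), "n_patients")
  expect_error(sim_config(lab_capture_prob = 1.2), "probabilities")
  expect_error(sim_config(true_t2d_prev = 0.999, true_t1d_prev = 0.5),
               "must not exceed 1")
  mix <- default_mix <- phenoequiv::sim_config()$stratum_mix
  mix$prob <- mix$prob * 2
  expect_error(sim_config(stratum_mix = mix), "sum to 1")
})

test_that("zero patients gives an empty, valid bundle and empty truth", {
  g <- generate_population(sim_config(n_patients = 0))
  expect_s3_class(g$bundle, "ehr_bundle")
  expect_equal(nrow(g$bundle$patients), 0L)
  expect_equal(nrow(g$truth), 0L)
  expect_silent(validate_bundle(g$bundle))
})

test_that("generation is deterministic given the seed, and round-trips", {
  cfg <- sim_config(n_patients = 400, seed = 77L)
  g1 <- generate_population(cfg)
  g2 <- generate_population(cfg)
  for (tb in c("patients", "encounters", "diagnoses", "labs",
               "medications", "pregnancies")) {
    expect_identical(g1$bundle[[tb]], g2$bundle[[tb]], info = tb)
  }
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_population(sim_config(n_patients = 400, seed = 78L))
  expect_false(identical(g1$bundle$labs, g3$bundle$labs))

  dir <- withr::local_tempdir()
  write_bundle(g1$bundle, dir)
  b2 <- load_bundle(dir)
  expect_equal(as.data.frame(b2$labs), as.data.frame(g1$bundle$labs))
  expect_equal(as.data.frame(b2$patients), as.data.frame(g1$bundle$patients))
})

test_that("truth_prevalence counts exactly and rejects empty strata", {
  truth <- data.table::data.table(
    patient_id = sprintf("p%d", 1:10),
    true_label = c(rep("t2d", 3), rep("none", 7)),
    sex = "female", age_group = "25-34", race_ethnicity = "white")
  expect_equal(truth_prevalence(truth, "overall"), 0.3)
  expect_equal(truth_prevalence(truth, c("age_group", "25-34")), 0.3)
  expect_error(truth_prevalence(truth, c("age_group", "35-44")), "empty stratum")
  truth$true_label <- "none"
  expect_equal(truth_prevalence(truth), 0)
})

test_that("empirical truth prevalence concentrates around the configured rate", {
  cfg <- sim_config(n_patients = 20000, seed = 5L,
                    true_t2d_prev = c(`18-24` = 0.02, `25-34` = 0.02,
                                      `35-44` = 0.02))
  g <- generate_population(cfg)
  p <- truth_prevalence(g$truth, "overall")
  tol <- 4 * sqrt(0.02 * 0.98 / 20000)
  expect_lt(abs(p - 0.02), tol)
})

test_that("lowering capture probabilities only removes records and detected cases", {
  base <- list(n_patients = 4000, seed = 11L)
  hi <- generate_population(do.call(sim_config, c(base, list(
    lab_capture_prob = 0.9, dx_capture_prob = 0.9, med_capture_prob = 0.7))))
  lo <- generate_population(do.call(sim_config, c(base, list(
    lab_capture_prob = 0.5, dx_capture_prob = 0.5, med_capture_prob = 0.3))))
  # common random numbers: the low-capture record set nests in the high one
  expect_true(nrow(lo$bundle$labs) <= nrow(hi$bundle$labs))
  expect_true(nrow(lo$bundle$diagnoses) <= nrow(hi$bundle$diagnoses))
  key <- function(tb) paste(tb$patient_id, tb$date, tb$code)
  expect_true(all(key(lo$bundle$diagnoses) %in% key(hi$bundle$diagnoses)))
  # detected (any-type) diabetes never increases when capture drops
  det <- function(b) {
    c(cp1 = sum(classify_cp1(b, 2022)$label != "none"),
      cp2_dm = sum(classify_cp2(b, 2022)$label != "none"))
  }
  expect_true(all(det(lo$bundle) <= det(hi$bundle)))
})

test_that("catchment fraction shapes the CP 1 denominator", {
  cfg <- sim_config(n_patients = 20000, seed = 9L, catchment_fraction = 0.44)
  g <- generate_population(cfg)
  n1 <- length(eligible_patients(g$bundle, "cp1", 2022))
  n2 <- length(eligible_patients(g$bundle, "cp2", 2022))
  # expected ratio: f scaled by the chance of >=1 encounter in 2 vs 3 years
  r <- cfg$encounter_rate
  expected <- 0.44 * (1 - exp(-2 * r)) / (1 - exp(-3 * r))
  expect_lt(abs(n1 / n2 - expected), 0.02)
})

test_that("perfect observation lets both phenotypes recover every truth label", {
  cfg <- sim_config(n_patients = 3000, seed = 21L, lab_capture_prob = 1,
                    med_capture_prob = 1, dx_capture_prob = 1,
                    type_miscode_prob = 0)
  g <- generate_population(cfg)
  l1 <- classify_cp1(g$bundle, 2022)
  l2 <- classify_cp2(g$bundle, 2022)
  truth <- g$truth[order(patient_id)]
  expect_identical(l1[order(patient_id)]$label, truth$true_label)
  expect_identical(l2[order(patient_id)]$label, truth$true_label)
})
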