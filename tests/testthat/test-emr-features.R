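demoVocab <- list(gender = c("female", "male"),
                  race = c("Asian", "Black", "White"),
                  smoking = c("current", "former", "never"))

test_that("demographics one-hot encoding hits one level per block plus age", {
  rec <- data.frame(gender = "female", race = "White", smoking = "never",
                    age = 66.14)
  v <- encodeDemographics(rec, demoVocab)
  expect_equal(unname(v["gender_female"]), 1)
  expect_equal(unname(v["race_White"]), 1)
  expect_equal(unname(v["smoking_never"]), 1)
  expect_equal(unname(v["age"]), 66.14)
  # exactly one 1 per categorical block
  for (f in c("gender", "race", "smoking")) {
    block <- v[startsWith(names(v), paste0(f, "_"))]
    expect_equal(sum(block), 1)
  }
})

test_that("unseen levels map to the explicit unknown column", {
  rec <- data.frame(gender = "female", race = "Martian", smoking = "never",
                    age = 40)
  v <- encodeDemographics(rec, demoVocab)
  expect_equal(unname(v["race_unknown"]), 1)
  expect_equal(sum(v[startsWith(names(v), "race_")]), 1)
})

test_that("negative age is rejected and missing records mark unknowns", {
  rec <- data.frame(gender = "male", race = "White", smoking = "never",
                    age = -3)
  expect_error(encodeDemographics(rec, demoVocab), "age")
  v <- encodeDemographics(NULL, demoVocab)
  expect_equal(unname(v["gender_unknown"]), 1)
  expect_true(is.na(v["age"]))
})

test_that("vital derivatives follow the finite-difference definition", {
  const <- data.frame(vital = "hr", time_days = c(-30, -20, -10),
                      value = c(70, 70, 70))
  v <- encodeVitals(const)
  expect_equal(unname(v["hr_dmean"]), 0)
  expect_equal(unname(v["hr_dmax"]), 0)
  expect_equal(unname(v["hr_last"]), 70)
  expect_equal(unname(v["hr_missing"]), 0)

  ramp <- data.frame(vital = "hr", time_days = c(0, 10) - 10,
                     value = c(70, 80))
  v <- encodeVitals(ramp)
  expect_equal(unname(v["hr_dmean"]), 1.0)   # 10 units over 10 days
  expect_equal(unname(v["hr_dmax"]), 1.0)
  expect_equal(unname(v["hr_last"]), 80)
})

test_that("degenerate vital series impute zero with a missingness flag", {
  single <- data.frame(vital = "hr", time_days = -5, value = 72)
  v <- encodeVitals(single)
  expect_equal(unname(v["hr_dmean"]), 0)
  expect_equal(unname(v["hr_missing"]), 1)
  expect_equal(unname(v["hr_last"]), 72)
  # absent vital: flagged missing, last value NA for later imputation
  expect_true(is.na(v["sbp_last"]))
  expect_equal(unname(v["sbp_missing"]), 1)
})

test_that("non-monotone vital timestamps are rejected", {
  bad <- data.frame(vital = "hr", time_days = c(-5, -10), value = c(70, 75))
  expect_error(encodeVitals(bad), "non-monotone")
})

test_that("medication encoding yields (count, presence) pairs per class", {
  vocab <- c("A", "B", "C")
  empty <- encodeMedications(data.frame(drug_class = character(),
                                        time_days = numeric()), vocab)
  expect_true(all(empty == 0))

  orders <- data.frame(drug_class = c("A", "A", "A", "B"),
                       time_days = c(-1, -2, -3, -4))
  v <- encodeMedications(orders, vocab)
  expect_equal(unname(v[c("A_count", "A_presence", "B_count", "B_presence",
                          "C_count", "C_presence")]),
               c(3, 1, 1, 1, 0, 0))

  unknown <- data.frame(drug_class = c("A", "Z"), time_days = c(-1, -2))
  expect_warning(v2 <- encodeMedications(unknown, vocab), "Z")
  expect_equal(unname(v2["A_count"]), 1)
  expect_false(any(startsWith(names(v2), "Z")))
})

test_that("the ICD leakage filter drops exam-encounter and <24h codes", {
  codes <- data.frame(
    code = c("G01.1", "G02.1", "G03.1", "G04.1"),
    time_days = c(-40, -23 / 24, -25 / 24, -1),
    encounter_id = c("E1", "E2", "E3", "E4"))
  kept <- filterICDLeakage(codes, studyEncounterId = "E9")
  # 23h before: dropped; 25h before: kept; exactly 24h: kept
  expect_setequal(kept$code, c("G01.1", "G03.1", "G04.1"))

  sameEnc <- data.frame(code = "G05.1", time_days = -100,
                        encounter_id = "E9")
  expect_equal(nrow(filterICDLeakage(sameEnc, "E9")), 0)

  unverifiable <- data.frame(code = "G06.1", time_days = NA_real_,
                             encounter_id = NA_character_)
  expect_warning(out <- filterICDLeakage(unverifiable, "E9"),
                 "lack both timestamp and encounter")
  expect_equal(nrow(out), 0)
})

test_that("encodeICD groups codes after filtering", {
  vocab <- c("G01", "G02")
  codes <- data.frame(code = c("G01.1", "G01.3", "G02.2", "G09.1"),
                      time_days = c(-40, -50, -60, -70),
                      encounter_id = paste0("E", 1:4))
  v <- encodeICD(codes, "E9", 0, vocab)
  expect_equal(unname(v[c("G01_presence", "G01_count",
                          "G02_presence", "G02_count")]),
               c(1, 2, 1, 1))
})

test_that("rare ICD groups are excluded from the fitted vocabulary", {
  # 200 synthetic training studies; group GRARE occurs in exactly 1 (0.5%),
  # GBOUND in exactly 2 (1.0%), GCOMMON in half of them
  mkStudy <- function(i) {
    codes <- data.frame(code = character(), time_days = numeric(),
                        encounter_id = character())
    if (i <= 100) codes <- rbind(codes, data.frame(
      code = "GCOMMON.1", time_days = -50, encounter_id = "EZ"))
    if (i == 1) codes <- rbind(codes, data.frame(
      code = "GRARE.1", time_days = -60, encounter_id = "EZ"))
    if (i <= 2) codes <- rbind(codes, data.frame(
      code = "GBOUND.1", time_days = -70, encounter_id = "EZ"))
    new("SyntheticStudy", patientId = sprintf("P%03d", i),
        studyId = sprintf("S%03d", i), split = "train",
        label = if (i %% 2 == 0) 1L else 0L,
        peExtent = if (i %% 2 == 0) "segmental" else "none",
        sliceLabels = if (i %% 2 == 0) c(rep(1L, 12), rep(0L, 12))
                      else integer(24),
        volume = array(0L, c(4, 4, 24)),
        emr = list(demographics = NULL, vitals = NULL, medications = NULL,
                   icd = codes, labs = NULL)[emrCategories()],
        encounterId = sprintf("X%03d", i))
  }
  studies <- lapply(1:200, mkStudy)
  schema <- fitEMRSchema(studies, icdMinFrequency = 0.01)
  expect_true("GCOMMON" %in% schema@vocab$icd)
  expect_true("GBOUND" %in% schema@vocab$icd)   # exactly 1% is kept
  expect_false("GRARE" %in% schema@vocab$icd)   # below 1% is excluded
})

test_that("lab encoding keeps the latest value with deterministic ties", {
  vocab <- c("DDIMER", "TROP")
  res <- data.frame(test_id = c("DDIMER", "DDIMER"),
                    time_days = c(-30, -5), value = c(400, 900))
  v <- encodeLabs(res, vocab)
  expect_equal(unname(v[c("DDIMER_presence", "DDIMER_last")]), c(1, 900))
  expect_equal(unname(v["TROP_presence"]), 0)
  expect_true(is.na(v["TROP_last"]))

  none <- encodeLabs(data.frame(test_id = character(),
                                time_days = numeric(),
                                value = numeric()), vocab)
  expect_true(all(none[endsWith(names(none), "_presence")] == 0))

  tied <- data.frame(test_id = c("DDIMER", "DDIMER"),
                     time_days = c(-5, -5), value = c(100, 200))
  expect_warning(vt <- encodeLabs(tied, vocab), "tied")
  expect_equal(unname(vt["DDIMER_last"]), 200)  # later record wins

  bad <- data.frame(test_id = "DDIMER", time_days = -5, value = "high")
  expect_error(encodeLabs(bad, vocab), "numeric")
})

test_that("fitted schemas z-normalise the training split", {
  co <- smallCohort()
  schema <- fitEMRSchema(co)
  m <- emrFeatureMatrix(co, schema, split = "train")
  mu <- colMeans(m)
  sds <- apply(m, 2, sd)
  expect_lt(max(abs(mu)), 1e-6)
  # features without missingness or degeneracy have unit SD; imputed or
  # constant features may have less, never more (up to sampling factor)
  expect_lt(max(sds), 1 + 1e-6)
  expect_true(any(abs(sds - 1) < 1e-6))
})

test_that("zero-variance features are centered, not scaled", {
  vocab <- list(gender = "female", race = "White", smoking = "never")
  mk <- function(i, age) {
    new("SyntheticStudy", patientId = paste0("P", i),
        studyId = paste0("S", i), split = "train",
        label = (i %% 2 == 0) * 1L,
        peExtent = if (i %% 2 == 0) "central" else "none",
        sliceLabels = if (i %% 2 == 0) c(rep(1L, 12), rep(0L, 12))
                      else integer(24),
        volume = array(0L, c(4, 4, 24)),
        emr = list(demographics = data.frame(gender = "female",
                                             race = "White",
                                             smoking = "never", age = age),
                   vitals = NULL, medications = NULL, icd = NULL,
                   labs = NULL)[emrCategories()],
        encounterId = paste0("X", i))
  }
  studies <- lapply(1:6, function(i) mk(i, age = 50))  # constant age
  schema <- fitEMRSchema(studies)
  v <- transformEMR(studies[[1]], schema)
  expect_equal(unname(v["age"]), 0)   # centered to 0, not divided
  st <- schema@stats$demographics
  expect_equal(st$sd[st$name == "age"], 0)
})

test_that("schemas are frozen: test data never influence them", {
  co <- smallCohort()
  schema1 <- fitEMRSchema(co)
  # perturb every non-training study drastically
  co2 <- co
  for (i in seq_along(co2@studies)) {
    if (co2@studies[[i]]@split != "train") {
      st <- co2@studies[[i]]
      st@emr <- lapply(st@emr, function(x) NULL)[emrCategories()]
      co2@studies[[i]] <- st
    }
  }
  schema2 <- fitEMRSchema(co2)
  expect_identical(schema1@vocab, schema2@vocab)
  expect_identical(schema1@stats, schema2@stats)
})

test_that("transformEMR is a pure function of study and schema", {
  co <- smallCohort()
  schema <- fitEMRSchema(co)
  st <- co[[1]]
  expect_identical(transformEMR(st, schema), transformEMR(st, schema))
})

test_that("drug classes unseen in training are ignored at transform time", {
  co <- smallCohort()
  schema <- fitEMRSchema(co)
  testIdx <- which(splits(co) == "test")[1]
  st <- co[[testIdx]]
  if (is.null(st@emr$medications)) {
    st@emr$medications <- data.frame(drug_class = character(),
                                     time_days = numeric())
  }
  base <- transformEMR(st, schema)
  st@emr$medications <- rbind(st@emr$medications,
                              data.frame(drug_class = "NOVELCLASS",
                                         time_days = -10))
  expect_identical(transformEMR(st, schema), base)
})
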