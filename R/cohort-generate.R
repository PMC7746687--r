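# Synthetic cohort generation: volumes with an additive ellipsoidal lesion
# over a contiguous run of positive slices, plus per-category EMR tables
# whose informative features shift with the study label. Image and EMR
# signals are conditionally independent given the label, so fusion gains
# are expected by construction.

.VITALS <- data.frame(
  vital = c("sbp", "dbp", "height", "weight", "bmi", "temp", "resp",
            "spo2", "hr"),
  base  = c(122, 78, 168, 78, 28.4, 36.8, 16, 97, 81.6),
  sd    = c(15, 10, 10, 15, 9.6, 0.4, 3, 2, 15),
  # direction of the label-linked drift; 0 = uninformative vital
  drift = c(0, 0, 0, 0, 0, 0, 1, -1, 1),
  stringsAsFactors = FALSE
)

.MED_CLASSES <- sprintf("MED%02d", 1:16)
.MED_SIGNAL <- c("MED01", "MED02", "MED03")   # label-linked drug classes
.ICD_GROUPS <- sprintf("G%02d", 1:12)
.ICD_SIGNAL <- c("G01", "G02", "G03")         # label-linked diagnosis groups
.LAB_TESTS <- c("DDIMER", sprintf("LAB%02d", 2:10))
.LAB_SIGNAL <- c("DDIMER", "LAB02")           # label-linked lab tests
.EMR_WINDOW_DAYS <- 365                        # 12-month observational window

.emptyEMRTable <- function(category) {
  switch(category,
    demographics = data.frame(gender = character(), race = character(),
                              smoking = character(), age = numeric(),
                              stringsAsFactors = FALSE),
    vitals = data.frame(vital = character(), time_days = numeric(),
                        value = numeric(), stringsAsFactors = FALSE),
    medications = data.frame(drug_class = character(), time_days = numeric(),
                             stringsAsFactors = FALSE),
    icd = data.frame(code = character(), time_days = numeric(),
                     encounter_id = character(), stringsAsFactors = FALSE),
    labs = data.frame(test_id = character(), time_days = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
}

# Background volume: air border, soft-tissue body ellipse, two low-density
# lung ellipses, a posterior high-density spine block (values beyond the
# 900 HU clip bound, so clipping is exercised), plus Gaussian noise.
.backgroundVolume <- function(h, w, nSlices) {
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  body <- ((ii - cy) / (0.46 * h))^2 + ((jj - cx) / (0.46 * w))^2 <= 1
  lungL <- ((ii - cy) / (0.30 * h))^2 + ((jj - 0.32 * w) / (0.17 * w))^2 <= 1
  lungR <- ((ii - cy) / (0.30 * h))^2 + ((jj - 0.68 * w) / (0.17 * w))^2 <= 1
  spine <- ((ii - 0.85 * h) / (0.06 * h))^2 + ((jj - cx) / (0.06 * w))^2 <= 1
  slice <- matrix(-1000, h, w)
  slice[body] <- 40
  slice[lungL | lungR] <- -800
  slice[spine & body] <- 1200
  vol <- array(rep(slice, nSlices), dim = c(h, w, nSlices))
  vol + array(stats::rnorm(h * w * nSlices, sd = 60), dim = dim(vol))
}

# Additive bright ellipsoid centred in one lung, spanning exactly the
# contiguous run of positive slices.
.addLesion <- function(vol, sliceRun, amplitude) {
  d <- dim(vol)
  h <- d[1]; w <- d[2]
  lung <- if (stats::runif(1) < 0.5) 0.32 else 0.68
  cy <- (0.5 + stats::runif(1, -0.15, 0.15)) * h
  cx <- (lung + stats::runif(1, -0.06, 0.06)) * w
  rxy <- max(2, 0.11 * min(h, w))
  cz <- mean(sliceRun)
  rz <- (length(sliceRun)) / 2 + 0.5
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (s in sliceRun) {
    dz2 <- ((s - cz) / rz)^2
    if (dz2 >= 1) next
    d2 <- ((ii - cy) / rxy)^2 + ((jj - cx) / rxy)^2 + dz2
    vol[, , s] <- vol[, , s] + amplitude * pmax(0, 1 - d2)
  }
  vol
}

.genDemographics <- function(label, effect) {
  # PE risk increases with age; the shift is the category's effect knob
  age <- stats::rnorm(1, 62 + 8 * effect * label, 16)
  age <- min(max(age, 18), 100)
  data.frame(
    gender = sample(c("female", "male"), 1, prob = c(0.57, 0.43)),
    race = sample(c("White", "Black", "Asian", "Pacific Islander", "Other",
                    "Unknown"), 1,
                  prob = c(0.597, 0.076, 0.078, 0.007, 0.114, 0.128)),
    smoking = sample(c("never", "former", "current"), 1,
                     prob = c(0.5, 0.3, 0.2)),
    age = round(age, 2),
    stringsAsFactors = FALSE)
}

.genVitals <- function(label, effect, noiseSd) {
  rows <- lapply(seq_len(nrow(.VITALS)), function(i) {
    v <- .VITALS[i, ]
    n <- 2L + stats::rpois(1, 4)
    t <- sort(stats::runif(n, -.EMR_WINDOW_DAYS, 0))
    base <- v$base + stats::rnorm(1, sd = 0.5 * v$sd)
    val <- base + stats::rnorm(n, sd = 0.3 * v$sd * noiseSd)
    if (v$drift != 0 && label == 1L) {
      # upward (or downward) ramp over the last 60 days before the exam
      ramp <- pmax(0, (t + 60) / 60)
      val <- val + v$drift * effect * v$sd * ramp
    }
    data.frame(vital = v$vital, time_days = round(t, 2),
               value = round(val, 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.genMedications <- function(label, effect) {
  baseRate <- stats::setNames(
    rep(c(0.5, 1.2, 0.3, 0.8), length.out = length(.MED_CLASSES)),
    .MED_CLASSES)
  rows <- lapply(.MED_CLASSES, function(cl) {
    rate <- baseRate[[cl]] *
      exp(if (cl %in% .MED_SIGNAL) effect * label else 0)
    k <- stats::rpois(1, rate)
    if (k == 0) return(NULL)
    data.frame(drug_class = cl,
               time_days = round(stats::runif(k, -.EMR_WINDOW_DAYS, 0), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .emptyEMRTable("medications") else out
}

.genICD <- function(label, effect, encounterId) {
  baseRate <- stats::setNames(
    rep(c(0.4, 0.9, 0.2, 0.6), length.out = length(.ICD_GROUPS)),
    .ICD_GROUPS)
  rows <- lapply(.ICD_GROUPS, function(g) {
    rate <- baseRate[[g]] *
      exp(if (g %in% .ICD_SIGNAL) effect * label else 0)
    k <- stats::rpois(1, rate)
    if (k == 0) return(NULL)
    data.frame(code = sprintf("%s.%d", g, sample(1:4, k, replace = TRUE)),
               time_days = round(stats::runif(k, -.EMR_WINDOW_DAYS, -1.5), 2),
               encounter_id = sprintf("E%s", substring(encounterId, 2)),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (!is.null(rows))
    rows$encounter_id <- paste0("ENC", sample(1e5, nrow(rows), replace = TRUE))
  # leakage rows that the encoder must drop: the exam-encounter diagnosis
  # (for positives this is the PE code itself) and a same-day code
  leak <- data.frame(
    code = if (label == 1L) "G99.1" else "G98.1",
    time_days = 0,
    encounter_id = encounterId,
    stringsAsFactors = FALSE)
  sameDay <- data.frame(
    code = sprintf("G%02d.1", sample(4:12, 1)),
    time_days = round(-stats::runif(1, 0, 0.9), 3),
    encounter_id = paste0("ENC", sample(1e5, 1)),
    stringsAsFactors = FALSE)
  out <- rbind(rows, leak, sameDay)
  rownames(out) <- NULL
  out
}

.genLabs <- function(label, effect, noiseSd) {
  presence <- stats::setNames(
    rep(c(0.35, 0.5, 0.25, 0.6), length.out = length(.LAB_TESTS)),
    .LAB_TESTS)
  presence["DDIMER"] <- 0.6
  base <- stats::setNames(seq(1, 10, length.out = length(.LAB_TESTS)),
                          .LAB_TESTS)
  rows <- lapply(.LAB_TESTS, function(tst) {
    if (stats::runif(1) > presence[[tst]]) return(NULL)
    k <- sample(1:3, 1)
    shift <- if (tst %in% .LAB_SIGNAL) effect * label else 0
    data.frame(test_id = tst,
               time_days = round(sort(stats::runif(k, -.EMR_WINDOW_DAYS, 0)), 2),
               value = round(base[[tst]] + shift +
                               stats::rnorm(k, sd = noiseSd), 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .emptyEMRTable("labs") else out
}

#' Generate a synthetic PE cohort
#'
#' @description
#' Generates a deterministic (seed-controlled) multi-patient cohort of CT
#' studies with slice-level lesion labels and per-category EMR tables.
#' Positive studies carry a contiguous run of positive slices whose voxels
#' receive an additive bright ellipsoidal lesion of amplitude
#' `imageEffect`; each EMR category's informative features shift with the
#' label by the category's effect size. Given the label, the imaging and
#' EMR signals are independent. Split assignment happens at the patient
#' level, so no patient appears in more than one split.
#'
#' @param spec A [CohortSpec-class] (see [cohortSpec()]).
#' @return A [PECohort-class].
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 12, seed = 3))
#' cohort
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  h <- spec@volumeShape[1]; w <- spec@volumeShape[2]
  studies <- list()
  studyCounter <- 0L
  for (p in seq_len(spec@nPatients)) {
    pid <- sprintf("P%04d", p)
    split <- sample(c("train", "validation", "test"), 1,
                    prob = spec@splitFractions)
    nStudies <- sample.int(spec@studiesPerPatientMax, 1)
    for (k in seq_len(nStudies)) {
      studyCounter <- studyCounter + 1L
      sid <- sprintf("S%04d", studyCounter)
      encId <- sprintf("X%04d", studyCounter)
      label <- as.integer(stats::runif(1) < spec@prevalence)
      sliceRange <- seq.int(spec@slicesPerStudy[1], spec@slicesPerStudy[2])
      nSlices <- sliceRange[sample.int(length(sliceRange), 1)]
      vol <- .backgroundVolume(h, w, nSlices)
      sliceLabels <- integer(nSlices)
      extent <- "none"
      if (label == 1L) {
        extent <- if (stats::runif(1) < spec@subsegmentalFraction)
          "subsegmental"
        else sample(c("central", "segmental"), 1, prob = c(0.399, 0.601))
        runCand <- 9:min(16L, nSlices)
        runLen <- runCand[sample.int(length(runCand), 1)]
        start <- sample.int(nSlices - runLen + 1L, 1)
        run <- start:(start + runLen - 1L)
        sliceLabels[run] <- 1L
        # lesion conspicuity varies between studies (contrast timing,
        # lesion size): a fraction of positives is nearly image-occult,
        # bounding the achievable imaging AUROC below 1 and creating the
        # image-miss subpopulation that clinical data can rescue
        conspicuity <- stats::runif(1, 0.15, 1.25)
        amp <- spec@imageEffect * conspicuity *
          (if (extent == "subsegmental") spec@subsegmentalAttenuation else 1)
        vol <- .addLesion(vol, run, amp)
      }
      storage.mode(vol) <- "double"
      vol <- array(as.integer(pmin(pmax(round(vol), -32768), 32767)),
                   dim = dim(vol))
      emr <- list()
      eff <- spec@emrEffect
      miss <- spec@missingness
      emr$demographics <- if (stats::runif(1) < miss[["demographics"]]) NULL
        else .genDemographics(label, eff[["demographics"]])
      emr$vitals <- if (stats::runif(1) < miss[["vitals"]]) NULL
        else .genVitals(label, eff[["vitals"]], spec@emrNoiseSd)
      emr$medications <- if (stats::runif(1) < miss[["medications"]]) NULL
        else .genMedications(label, eff[["medications"]])
      emr$icd <- if (stats::runif(1) < miss[["icd"]]) NULL
        else .genICD(label, eff[["icd"]], encId)
      emr$labs <- if (stats::runif(1) < miss[["labs"]]) NULL
        else .genLabs(label, eff[["labs"]], spec@emrNoiseSd)
      emr <- emr[emrCategories()]
      names(emr) <- emrCategories()
      studies[[sid]] <- new("SyntheticStudy",
        patientId = pid, studyId = sid, split = split, label = label,
        peExtent = extent, sliceLabels = sliceLabels, volume = vol,
        emr = emr, encounterId = encId)
    }
  }
  new("PECohort", studies = unname(studies), spec = spec)
}
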