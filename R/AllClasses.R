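#' @import methods
NULL

#' EMR categories used throughout the package
#'
#' The five structured EMR categories, in the fixed concatenation order used
#' for feature vectors: demographics, vitals, medications, ICD diagnosis
#' codes, labs.
#'
#' @return Character vector of category names.
#' @export
emrCategories <- function() {
  c("demographics", "vitals", "medications", "icd", "labs")
}

#' Cohort specification for the synthetic generator
#'
#' @description
#' A `CohortSpec` fixes every parameter of a synthetic pulmonary-embolism
#' cohort: cohort size, PE prevalence, volume geometry, the imaging lesion
#' contrast, the per-category EMR effect sizes (log-odds-scale shifts of the
#' informative features), category-level missingness, and the fraction of
#' positive studies whose largest defect is subsegmental. The `seed` fully
#' determines the generated cohort.
#'
#' @slot nPatients Number of patients (at least 3, to populate three splits).
#' @slot studiesPerPatientMax Maximum CT studies per patient (default 1).
#' @slot prevalence Fraction of positive studies, strictly in (0, 1).
#' @slot slicesPerStudy Integer range (min, max) of axial slices per study.
#' @slot volumeShape In-plane volume dimensions (height, width) in voxels.
#' @slot imageEffect Additive lesion contrast in Hounsfield-like units
#'   (>= 0; 0 means no imaging signal).
#' @slot emrEffect Named numeric vector of per-category effect sizes (>= 0),
#'   names from [emrCategories()].
#' @slot emrNoiseSd Residual noise scale of the informative EMR features.
#' @slot missingness Named per-category probability that a study lacks the
#'   category entirely, each in [0, 1).
#' @slot subsegmentalFraction Fraction of positive studies flagged
#'   subsegmental-only, in [0, 1).
#' @slot subsegmentalAttenuation Multiplier on `imageEffect` for
#'   subsegmental positives (1 = lesion contrast independent of extent;
#'   values < 1 emulate the harder-to-see small emboli).
#' @slot splitFractions Patient-level probabilities of the train /
#'   validation / test splits.
#' @slot seed Integer seed; the same spec generates byte-identical cohorts.
#'
#' @seealso [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nPatients = "integer",
    studiesPerPatientMax = "integer",
    prevalence = "numeric",
    slicesPerStudy = "integer",
    volumeShape = "integer",
    imageEffect = "numeric",
    emrEffect = "numeric",
    emrNoiseSd = "numeric",
    missingness = "numeric",
    subsegmentalFraction = "numeric",
    subsegmentalAttenuation = "numeric",
    splitFractions = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 3L)
    msg <- c(msg, "nPatients must be >= 3 (cannot populate three splits)")
  if (object@studiesPerPatientMax < 1L)
    msg <- c(msg, "studiesPerPatientMax must be >= 1")
  if (!(object@prevalence > 0 && object@prevalence < 1))
    msg <- c(msg, "prevalence must lie strictly in (0, 1)")
  if (length(object@slicesPerStudy) != 2L ||
      any(object@slicesPerStudy < 1L) ||
      object@slicesPerStudy[1] > object@slicesPerStudy[2])
    msg <- c(msg, "slicesPerStudy must be an increasing (min, max) pair")
  if (length(object@volumeShape) != 2L || any(object@volumeShape < 8L))
    msg <- c(msg, "volumeShape must be (height, width), each >= 8")
  if (object@imageEffect < 0)
    msg <- c(msg, "imageEffect must be >= 0")
  if (!setequal(names(object@emrEffect), emrCategories()) ||
      any(object@emrEffect < 0))
    msg <- c(msg, "emrEffect must be a non-negative vector named by the five EMR categories")
  if (object@emrNoiseSd <= 0)
    msg <- c(msg, "emrNoiseSd must be > 0")
  if (!setequal(names(object@missingness), emrCategories()) ||
      any(object@missingness < 0 | object@missingness >= 1))
    msg <- c(msg, "missingness must be named per-category fractions in [0, 1)")
  if (object@subsegmentalFraction < 0 || object@subsegmentalFraction >= 1)
    msg <- c(msg, "subsegmentalFraction must lie in [0, 1)")
  if (object@subsegmentalAttenuation < 0 || object@subsegmentalAttenuation > 1)
    msg <- c(msg, "subsegmentalAttenuation must lie in [0, 1]")
  if (length(object@splitFractions) != 3L ||
      any(object@splitFractions <= 0) ||
      abs(sum(object@splitFractions) - 1) > 1e-8)
    msg <- c(msg, "splitFractions must be three positive values summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a cohort specification
#'
#' Defaults describe the study conditions the package is exercised under: a
#' desk-scale cohort with ~40% PE prevalence (the prevalence of the clinical
#' cohort the design mirrors), one study per patient, 24-40 axial slices,
#' a visible but learnable lesion contrast, and EMR categories whose
#' predictive strength increases from demographics to labs (D-dimer being
#' the strongest single clinical signal for PE).
#'
#' @param nPatients Number of patients.
#' @param studiesPerPatientMax Maximum studies per patient.
#' @param prevalence Positive fraction in (0, 1).
#' @param slicesPerStudy Integer (min, max) slices per study.
#' @param volumeShape In-plane (height, width) in voxels.
#' @param imageEffect Lesion contrast in Hounsfield-like units.
#' @param emrEffect Named per-category effect sizes.
#' @param emrNoiseSd Noise SD of informative EMR features.
#' @param missingness Named per-category missingness fractions.
#' @param subsegmentalFraction Fraction of positives flagged subsegmental.
#' @param subsegmentalAttenuation Lesion-contrast multiplier for
#'   subsegmental positives (1 = independent of extent).
#' @param splitFractions Train/validation/test patient-level probabilities.
#' @param seed Integer seed.
#'
#' @return A [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(nPatients = 20, seed = 7)
#' spec
#' @export
cohortSpec <- function(nPatients = 150L,
                       studiesPerPatientMax = 1L,
                       prevalence = 0.4,
                       slicesPerStudy = c(24L, 40L),
                       volumeShape = c(32L, 32L),
                       imageEffect = 150,
                       emrEffect = c(demographics = 0.24, vitals = 0.48,
                                     medications = 0.72, icd = 0.96,
                                     labs = 1.2),
                       emrNoiseSd = 1,
                       missingness = c(demographics = 0.02, vitals = 0.05,
                                       medications = 0.1, icd = 0.1,
                                       labs = 0.15),
                       subsegmentalFraction = 0.113,
                       subsegmentalAttenuation = 1,
                       splitFractions = c(train = 0.6, validation = 0.2,
                                          test = 0.2),
                       seed = 1L) {
  new("CohortSpec",
      nPatients = as.integer(nPatients),
      studiesPerPatientMax = as.integer(studiesPerPatientMax),
      prevalence = as.numeric(prevalence),
      slicesPerStudy = as.integer(slicesPerStudy),
      volumeShape = as.integer(volumeShape),
      imageEffect = as.numeric(imageEffect),
      emrEffect = emrEffect[emrCategories()],
      emrNoiseSd = as.numeric(emrNoiseSd),
      missingness = missingness[emrCategories()],
      subsegmentalFraction = as.numeric(subsegmentalFraction),
      subsegmentalAttenuation = as.numeric(subsegmentalAttenuation),
      splitFractions = as.numeric(splitFractions),
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatients, "patients, prevalence",
      object@prevalence, "\n")
  cat("  volume", paste(object@volumeShape, collapse = "x"), "x",
      paste(object@slicesPerStudy, collapse = "-"),
      "slices; imageEffect", object@imageEffect, "HU\n")
  cat("  emrEffect:", paste(names(object@emrEffect), object@emrEffect,
                            sep = "=", collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

#' A single synthetic CT study with EMR records
#'
#' @description
#' One CT examination: patient/study identifiers, split assignment,
#' study-level PE label, PE extent (central / segmental / subsegmental /
#' none), per-slice lesion labels, the voxel volume in Hounsfield-like
#' units, and the raw per-category EMR tables. The study label is 1 iff at
#' least one slice label is 1, and `peExtent == "none"` iff the label is 0.
#' All EMR record times lie within the 12 months before the examination
#' (time is expressed in days relative to the exam, so all offsets lie in
#' [-365, 0]).
#'
#' @slot patientId,studyId Character identifiers.
#' @slot split One of "train", "validation", "test".
#' @slot label Integer 0/1 study-level PE label.
#' @slot peExtent One of "central", "segmental", "subsegmental", "none".
#' @slot sliceLabels Integer 0/1 vector, one entry per axial slice.
#' @slot volume Integer voxel array (height x width x slices),
#'   Hounsfield-like units quantised to 16-bit integers.
#' @slot emr Named list of per-category data frames; `NULL` entries mark
#'   categories missing for this study.
#' @slot encounterId Encounter identifier of the CT examination (used by the
#'   ICD leakage filter).
#'
#' @export
setClass("SyntheticStudy",
  representation(
    patientId = "character",
    studyId = "character",
    split = "character",
    label = "integer",
    peExtent = "character",
    sliceLabels = "integer",
    volume = "array",
    emr = "list",
    encounterId = "character"
  )
)

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  if (!object@split %in% c("train", "validation", "test"))
    msg <- c(msg, "split must be train/validation/test")
  if (!object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 or 1")
  if (!object@peExtent %in% c("central", "segmental", "subsegmental", "none"))
    msg <- c(msg, "invalid peExtent")
  if ((object@label == 1L) != any(object@sliceLabels == 1L))
    msg <- c(msg, "label must be 1 iff at least one slice label is 1")
  if ((object@label == 0L) != (object@peExtent == "none"))
    msg <- c(msg, "peExtent must be 'none' iff label is 0")
  if (length(dim(object@volume)) != 3L)
    msg <- c(msg, "volume must be a 3-D array")
  if (dim(object@volume)[3] != length(object@sliceLabels))
    msg <- c(msg, "sliceLabels length must equal the number of slices")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy", object@studyId, "(patient", object@patientId,
      ",", object@split, ")\n")
  cat("  label:", object@label, " extent:", object@peExtent,
      " slices:", length(object@sliceLabels),
      sprintf(" (%d positive)\n", sum(object@sliceLabels)))
})

#' A synthetic PE cohort
#'
#' An ordered collection of [SyntheticStudy-class] objects together with the
#' [CohortSpec-class] that generated it. Supports `length()`, `[`, `[[` and
#' the accessors [studyIds()], [patientIds()], [splits()], [labels()],
#' [peExtent()].
#'
#' @slot studies List of [SyntheticStudy-class].
#' @slot spec The generating [CohortSpec-class].
#' @export
setClass("PECohort",
  representation(studies = "list", spec = "CohortSpec"))

setValidity("PECohort", function(object) {
  if (!all(vapply(object@studies, is, logical(1), "SyntheticStudy")))
    return("all elements must be SyntheticStudy objects")
  ids <- vapply(object@studies, function(s) s@studyId, character(1))
  if (anyDuplicated(ids)) return("study ids must be unique")
  # patient-level split integrity: a patient appears in exactly one split
  pid <- vapply(object@studies, function(s) s@patientId, character(1))
  spl <- vapply(object@studies, function(s) s@split, character(1))
  if (any(tapply(spl, pid, function(x) length(unique(x))) > 1L))
    return("patient ids must not overlap between splits")
  TRUE
})

#' @describeIn PECohort Number of studies in the cohort.
#' @param x A `PECohort`.
#' @export
setMethod("length", "PECohort", function(x) length(x@studies))

#' @export
setMethod("[[", "PECohort", function(x, i) x@studies[[i]])

#' @export
setMethod("[", "PECohort", function(x, i) {
  new("PECohort", studies = x@studies[i], spec = x@spec)
})

setMethod("show", "PECohort", function(object) {
  spl <- splits(object)
  lab <- labels(object)
  cat("PECohort with", length(object), "studies from",
      length(unique(patientIds(object))), "patients\n")
  for (s in c("train", "validation", "test")) {
    n <- sum(spl == s)
    cat(sprintf("  %-10s %3d studies (%d positive)\n", s, n,
                sum(lab[spl == s])))
  }
})

#' @rdname cohort-accessors
#' @title Cohort accessors
#' @description Vectorised accessors over the studies of a [PECohort-class].
#' @param x A `PECohort`.
#' @return A vector with one entry per study.
#' @export
studyIds <- function(x) vapply(x@studies, function(s) s@studyId, character(1))

#' @rdname cohort-accessors
#' @export
patientIds <- function(x) vapply(x@studies, function(s) s@patientId, character(1))

#' @rdname cohort-accessors
#' @export
splits <- function(x) vapply(x@studies, function(s) s@split, character(1))

#' @rdname cohort-accessors
#' @export
setGeneric("labels")

#' @rdname cohort-accessors
#' @export
setMethod("labels", "PECohort", function(object, ...) {
  stats::setNames(vapply(object@studies, function(s) s@label, integer(1)),
                  studyIds(object))
})

#' @rdname cohort-accessors
#' @export
peExtent <- function(x) {
  stats::setNames(vapply(x@studies, function(s) s@peExtent, character(1)),
                  studyIds(x))
}

#' @rdname cohort-accessors
#' @param split One of "train", "validation", "test".
#' @export
cohortSubset <- function(x, split) {
  stopifnot(split %in% c("train", "validation", "test"))
  x[splits(x) == split]
}

#' Per-study model predictions on one split
#'
#' Probabilities in [0, 1] from one model on one split, keyed by study id.
#'
#' @slot modelName Model identifier.
#' @slot split Which split the predictions refer to.
#' @slot studyIds Unique study identifiers.
#' @slot probabilities Predicted PE probabilities, aligned with `studyIds`.
#' @export
setClass("PredictionSet",
  representation(modelName = "character", split = "character",
                 studyIds = "character", probabilities = "numeric"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  if (length(object@studyIds) != length(object@probabilities))
    msg <- c(msg, "studyIds and probabilities must have equal length")
  if (anyDuplicated(object@studyIds))
    msg <- c(msg, "study ids must be unique")
  p <- object@probabilities
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    msg <- c(msg, "probabilities must be finite and in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionSet
#'
#' @param probabilities Numeric probabilities in [0, 1]; if `studyIds` is
#'   missing, names of `probabilities` are used.
#' @param modelName,split Identifiers stored with the set.
#' @param studyIds Study identifiers aligned with `probabilities`.
#' @return A [PredictionSet-class].
#' @export
predictionSet <- function(probabilities, modelName = "model",
                          split = "test", studyIds = names(probabilities)) {
  new("PredictionSet", modelName = modelName, split = split,
      studyIds = as.character(studyIds),
      probabilities = unname(as.numeric(probabilities)))
}

#' @rdname predictionSet
#' @param x A `PredictionSet`.
#' @return `probabilities()` returns the named probability vector.
#' @export
probabilities <- function(x) stats::setNames(x@probabilities, x@studyIds)

setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet:", object@modelName, "on", object@split, "split,",
      length(object@studyIds), "studies\n")
  cat("  prob range:",
      sprintf("[%.3f, %.3f]\n", min(object@probabilities),
              max(object@probabilities)))
})

#' @export
setMethod("length", "PredictionSet", function(x) length(x@studyIds))

#' Evaluation report at a fixed operating point
#'
#' AUROC with DeLong and bootstrap 95% intervals, plus threshold-dependent
#' metrics (sensitivity, specificity, accuracy, PPV, NPV) with Wilson score
#' intervals, for one model on one split and one subgroup variant.
#'
#' @slot modelName,split Identifiers.
#' @slot subgroup "all" or "excluding_subsegmental".
#' @slot threshold Operating threshold in [0, 1].
#' @slot auroc AUROC point estimate.
#' @slot aurocDeLongCI,aurocBootCI Length-2 95% intervals.
#' @slot metrics data.frame with columns metric, estimate, lower, upper,
#'   successes, trials.
#' @slot n Number of studies evaluated.
#' @slot nBoot Bootstrap replicates used.
#' @export
setClass("EvalReport",
  representation(modelName = "character", split = "character",
                 subgroup = "character", threshold = "numeric",
                 auroc = "numeric", aurocDeLongCI = "numeric",
                 aurocBootCI = "numeric", metrics = "data.frame",
                 n = "integer", nBoot = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  ok <- function(ci, point) length(ci) == 2 &&
    (all(is.na(ci)) || (ci[1] <= point + 1e-12 && point <= ci[2] + 1e-12))
  if (!ok(object@aurocDeLongCI, object@auroc))
    msg <- c(msg, "DeLong CI must bracket the AUROC")
  if (!ok(object@aurocBootCI, object@auroc))
    msg <- c(msg, "bootstrap CI must bracket the AUROC")
  if (object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %s on %s split (%s), n = %d\n",
              object@modelName, object@split, object@subgroup, object@n))
  cat(sprintf("  threshold %.3f\n", object@threshold))
  cat(sprintf("  AUROC %.3f [DeLong %.3f-%.3f] [boot %.3f-%.3f]\n",
              object@auroc, object@aurocDeLongCI[1], object@aurocDeLongCI[2],
              object@aurocBootCI[1], object@aurocBootCI[2]))
  m <- object@metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.3f [%.3f-%.3f]\n", m$metric[i], m$estimate[i],
                m$lower[i], m$upper[i]))
  }
})
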