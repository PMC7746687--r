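# EMR feature engineering. Each category of raw records is encoded to a
# fixed-length named sub-vector; vocabularies and normalisation statistics
# are fitted on the training split only and frozen in an EMRFeatureSchema.
# Missing raw values are encoded NA and imputed to 0 after centering (i.e.
# to the training mean), alongside explicit missingness indicator columns.

#' EMR feature schema
#'
#' Frozen per-category vocabularies, feature names and training-split
#' normalisation statistics. All schema content is derived from the
#' training split only; [transformEMR()] applies it unchanged to any split.
#'
#' @slot categories Category concatenation order.
#' @slot vocab Named list of per-category vocabularies.
#' @slot featureNames Named list of per-category feature name vectors.
#' @slot stats Named list of per-category data.frames (name, mean, sd).
#' @slot icdMinFrequency Minimum fraction of training studies an ICD group
#'   must occur in to enter the vocabulary (groups below it are excluded).
#' @slot nTrain Number of training studies the schema was fitted on.
#' @export
setClass("EMRFeatureSchema",
  representation(categories = "character", vocab = "list",
                 featureNames = "list", stats = "list",
                 icdMinFrequency = "numeric", nTrain = "integer"))

setMethod("show", "EMRFeatureSchema", function(object) {
  cat("EMRFeatureSchema fitted on", object@nTrain, "training studies\n")
  for (cat_ in object@categories)
    cat(sprintf("  %-13s %d features\n", cat_,
                length(object@featureNames[[cat_]])))
})

.DEMO_FIELDS <- c("gender", "race", "smoking")

.demoFeatureNames <- function(vocab) {
  nms <- unlist(lapply(.DEMO_FIELDS, function(f)
    paste(f, c(vocab[[f]], "unknown"), sep = "_")))
  c(nms, "age")
}

#' Encode demographics records
#'
#' One-hot encodes gender, race and smoking status against the schema
#' vocabulary (with an explicit `unknown` column per field for unseen
#' levels) and carries age as a numeric feature.
#'
#' @param records A one-row data.frame with columns gender, race, smoking,
#'   age; `NULL` or zero rows mark the category missing for the study.
#' @param vocabulary List with character vectors `gender`, `race`,
#'   `smoking` (the levels observed in training).
#' @return Named numeric sub-vector. A negative age is an error.
#' @export
encodeDemographics <- function(records, vocabulary) {
  nms <- .demoFeatureNames(vocabulary)
  out <- stats::setNames(numeric(length(nms)), nms)
  if (is.null(records) || nrow(records) == 0) {
    for (f in .DEMO_FIELDS) out[paste0(f, "_unknown")] <- 1
    out["age"] <- NA_real_
    return(out)
  }
  rec <- records[1, , drop = FALSE]
  for (f in .DEMO_FIELDS) {
    lvl <- as.character(rec[[f]])
    if (length(lvl) == 1 && !is.na(lvl) && lvl %in% vocabulary[[f]]) {
      out[paste(f, lvl, sep = "_")] <- 1
    } else {
      out[paste0(f, "_unknown")] <- 1
    }
  }
  age <- as.numeric(rec[["age"]])
  if (length(age) != 1 || (!is.na(age) && age < 0))
    stop("negative age in demographics record")
  out["age"] <- age
  out
}

.vitalFeatureNames <- function() {
  unlist(lapply(.VITALS$vital, function(v)
    paste(v, c("dmean", "dmax", "last", "missing"), sep = "_")))
}

#' Encode vital-sign time series
#'
#' Vitals are represented through their sensitivity to change: per vital,
#' the mean and maximum-absolute finite-difference derivative (per day)
#' over the 12-month window, the last observed value, and a missingness
#' indicator that is 1 when the derivative is undefined (fewer than two
#' observations).
#'
#' @param timeSeries data.frame with columns vital, time_days, value.
#'   Within each vital, `time_days` must be non-decreasing.
#' @return Named numeric sub-vector over the fixed clinical vital set
#'   (systolic/diastolic BP, height, weight, BMI, temperature, respiration
#'   rate, spO2, heart rate).
#' @export
encodeVitals <- function(timeSeries) {
  nms <- .vitalFeatureNames()
  out <- stats::setNames(numeric(length(nms)), nms)
  for (v in .VITALS$vital) {
    rows <- if (is.null(timeSeries) || nrow(timeSeries) == 0) NULL
            else timeSeries[timeSeries$vital == v, , drop = FALSE]
    if (is.null(rows) || nrow(rows) == 0) {
      out[paste0(v, "_last")] <- NA_real_
      out[paste0(v, "_missing")] <- 1
      next
    }
    t <- as.numeric(rows$time_days)
    if (is.unsorted(t))
      stop("non-monotone timestamps for vital '", v, "'")
    val <- as.numeric(rows$value)
    out[paste0(v, "_last")] <- val[length(val)]
    if (nrow(rows) < 2) {
      out[paste0(v, "_missing")] <- 1   # derivative undefined, imputed 0
      next
    }
    dt <- diff(t); dv <- diff(val)
    keep <- dt > 0
    if (!any(keep)) {
      out[paste0(v, "_missing")] <- 1
      next
    }
    deriv <- dv[keep] / dt[keep]
    out[paste0(v, "_dmean")] <- mean(deriv)
    out[paste0(v, "_dmax")] <- max(abs(deriv))
  }
  out
}

.medFeatureNames <- function(vocab) {
  unlist(lapply(vocab, function(cl) paste(cl, c("count", "presence"),
                                          sep = "_")))
}

#' Encode medication orders
#'
#' Each drug class in the vocabulary is represented as an order count
#' within the 12-month window and a binary prescribed/not label. Classes
#' absent from the vocabulary are ignored (optionally with a warning).
#'
#' @param orders data.frame with column drug_class (and time_days).
#' @param vocabulary Character vector of drug classes (training split).
#' @param warnUnknown Warn when orders carry classes outside the
#'   vocabulary (default TRUE; bulk transforms disable it).
#' @return Named numeric sub-vector `(count, presence)` per class.
#' @export
encodeMedications <- function(orders, vocabulary, warnUnknown = TRUE) {
  nms <- .medFeatureNames(vocabulary)
  out <- stats::setNames(numeric(length(nms)), nms)
  if (length(vocabulary) == 0 || is.null(orders) || nrow(orders) == 0)
    return(out)
  cls <- as.character(orders$drug_class)
  unknown <- setdiff(unique(cls), vocabulary)
  if (length(unknown) && warnUnknown)
    warning("ignoring drug class(es) outside vocabulary: ",
            paste(unknown, collapse = ", "))
  tab <- table(factor(cls, levels = vocabulary))
  out[paste0(vocabulary, "_count")] <- as.numeric(tab)
  out[paste0(vocabulary, "_presence")] <- as.numeric(tab > 0)
  out
}

#' Default ICD grouping: collapse a code to its top-level category
#'
#' Truncates a code at the first `.` (e.g. `"G01.3"` to `"G01"`),
#' emulating the collapse of diagnosis codes into top diagnosis
#' categories. Supply a different map to [fitEMRSchema()] for other
#' ontologies.
#'
#' @param code Character vector of diagnosis codes.
#' @return Character vector of group labels.
#' @export
icdTopLevelGroup <- function(code) sub("\\..*$", "", code)

#' Filter ICD codes for label leakage
#'
#' Drops every code recorded under the same encounter as the CT exam, and
#' every code timestamped within the 24 hours before the exam (strictly
#' less than 24 h; a code at exactly 24 h is kept). Codes missing both the
#' timestamp and the encounter id cannot be checked and are excluded with
#' a warning.
#'
#' @param codes data.frame with columns code, time_days (relative to the
#'   exam; negative = before), encounter_id.
#' @param studyEncounterId Encounter id of the CT exam.
#' @param studyTime Exam time in the same day units (default 0).
#' @return The filtered data.frame.
#' @export
filterICDLeakage <- function(codes, studyEncounterId, studyTime = 0) {
  if (is.null(codes) || nrow(codes) == 0) return(codes)
  t <- as.numeric(codes$time_days)
  enc <- as.character(codes$encounter_id)
  unverifiable <- is.na(t) & (is.na(enc) | enc == "")
  if (any(unverifiable))
    warning(sum(unverifiable),
            " ICD code(s) lack both timestamp and encounter id; excluded")
  sameEnc <- !is.na(enc) & enc == studyEncounterId
  diff <- studyTime - t
  within24h <- !is.na(t) & diff >= 0 & diff < 1
  keep <- !(unverifiable | sameEnc | within24h)
  out <- codes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.icdFeatureNames <- function(vocab) {
  unlist(lapply(vocab, function(g) paste(g, c("presence", "count"),
                                         sep = "_")))
}

#' Encode ICD diagnosis codes
#'
#' Applies the leakage filter ([filterICDLeakage()]) first, maps the
#' remaining codes to diagnosis groups, and emits a `(presence, count)`
#' pair per vocabulary group. Groups outside the vocabulary (rare in
#' training, or unseen) are ignored.
#'
#' @inheritParams filterICDLeakage
#' @param vocabulary Character vector of diagnosis groups (training split,
#'   after the minimum-frequency filter).
#' @param groupFun Code-to-group map (default [icdTopLevelGroup()]).
#' @return Named numeric sub-vector.
#' @export
encodeICD <- function(codes, studyEncounterId, studyTime = 0,
                      vocabulary, groupFun = icdTopLevelGroup) {
  nms <- .icdFeatureNames(vocabulary)
  out <- stats::setNames(numeric(length(nms)), nms)
  if (length(vocabulary) == 0) return(out)
  codes <- filterICDLeakage(codes, studyEncounterId, studyTime)
  if (is.null(codes) || nrow(codes) == 0) return(out)
  grp <- groupFun(as.character(codes$code))
  tab <- table(factor(grp, levels = vocabulary))
  out[paste0(vocabulary, "_presence")] <- as.numeric(tab > 0)
  out[paste0(vocabulary, "_count")] <- as.numeric(tab)
  out
}

.labFeatureNames <- function(vocab) {
  unlist(lapply(vocab, function(tst) paste(tst, c("presence", "last"),
                                           sep = "_")))
}

#' Encode lab results
#'
#' Each vocabulary test is represented as binary presence/absence and the
#' latest value by timestamp. Two results with identical timestamps are
#' tie-broken deterministically by record order (the later row wins) with
#' a warning. Absent tests get `(0, NA)`; the NA is imputed to the
#' training mean at normalisation.
#'
#' @param results data.frame with columns test_id, time_days, value.
#' @param vocabulary Character vector of lab test ids (training split).
#' @return Named numeric sub-vector. Non-numeric values are an error.
#' @export
encodeLabs <- function(results, vocabulary) {
  nms <- .labFeatureNames(vocabulary)
  out <- stats::setNames(numeric(length(nms)), nms)
  if (length(vocabulary) == 0) return(out)
  out[paste0(vocabulary, "_last")] <- NA_real_
  if (is.null(results) || nrow(results) == 0) return(out)
  if (!is.numeric(results$value))
    stop("lab values must be numeric")
  for (tst in intersect(unique(as.character(results$test_id)), vocabulary)) {
    rows <- results[results$test_id == tst, , drop = FALSE]
    t <- as.numeric(rows$time_days)
    latest <- which(t == max(t))
    if (length(latest) > 1)
      warning("tied timestamps for lab test '", tst,
              "'; keeping the last record in file order")
    out[paste0(tst, "_presence")] <- 1
    out[paste0(tst, "_last")] <- as.numeric(rows$value[latest[length(latest)]])
  }
  out
}

.encodeStudyRaw <- function(study, vocab, groupFun, warnUnknown = FALSE) {
  c(encodeDemographics(study@emr$demographics, vocab$demographics),
    encodeVitals(study@emr$vitals),
    encodeMedications(study@emr$medications, vocab$medications,
                      warnUnknown = warnUnknown),
    encodeICD(study@emr$icd, study@encounterId, 0,
              vocab$icd, groupFun = groupFun),
    encodeLabs(study@emr$labs, vocab$labs))
}

#' Fit an EMR feature schema on the training split
#'
#' Derives per-category vocabularies (demographic levels, drug classes,
#' lab tests, and ICD diagnosis groups passing the minimum-frequency
#' filter) and per-feature normalisation statistics from the training
#' studies only. ICD group frequency is counted as the fraction of
#' training studies containing the group after leakage filtering; groups
#' occurring in less than `icdMinFrequency` of training studies are
#' excluded from the vocabulary.
#'
#' @param cohort A [PECohort-class] (its training split is used) or a list
#'   of training [SyntheticStudy-class] objects.
#' @param icdMinFrequency Minimum per-study prevalence for an ICD group
#'   (default 0.01, i.e. 1%).
#' @param icdGroupFun Code-to-group map (default [icdTopLevelGroup()]).
#' @return An [EMRFeatureSchema-class].
#' @seealso [transformEMR()], [emrFeatureMatrix()]
#' @export
fitEMRSchema <- function(cohort, icdMinFrequency = 0.01,
                         icdGroupFun = icdTopLevelGroup) {
  train <- if (is(cohort, "PECohort")) cohortSubset(cohort, "train")@studies
           else cohort
  stopifnot(length(train) > 0)
  pick <- function(cat) lapply(train, function(s) s@emr[[cat]])

  demoTabs <- Filter(Negate(is.null), pick("demographics"))
  demoVocab <- lapply(stats::setNames(.DEMO_FIELDS, .DEMO_FIELDS),
    function(f) sort(unique(unlist(lapply(demoTabs,
      function(tab) as.character(tab[[f]]))))))

  medVocab <- sort(unique(unlist(lapply(pick("medications"),
    function(tab) if (is.null(tab)) NULL else as.character(tab$drug_class)))))

  labVocab <- sort(unique(unlist(lapply(pick("labs"),
    function(tab) if (is.null(tab)) NULL else as.character(tab$test_id)))))

  # ICD vocabulary: leakage-filter each study, then per-study group
  # prevalence over ALL training studies (missing-category studies count
  # in the denominator: the group did not occur there)
  groupsPerStudy <- lapply(train, function(s) {
    tab <- filterICDLeakage(s@emr$icd, s@encounterId, 0)
    if (is.null(tab) || nrow(tab) == 0) character(0)
    else unique(icdGroupFun(as.character(tab$code)))
  })
  prev <- table(unlist(groupsPerStudy)) / length(train)
  icdVocab <- sort(names(prev)[prev >= icdMinFrequency])

  vocab <- list(demographics = demoVocab, medications = medVocab,
                icd = icdVocab, labs = labVocab)
  featureNames <- list(
    demographics = .demoFeatureNames(demoVocab),
    vitals = .vitalFeatureNames(),
    medications = .medFeatureNames(medVocab),
    icd = .icdFeatureNames(icdVocab),
    labs = .labFeatureNames(labVocab))

  raw <- t(vapply(train,
                  function(s) .encodeStudyRaw(s, vocab, icdGroupFun),
                  numeric(sum(lengths(featureNames)))))
  statsList <- list()
  offset <- 0L
  for (cat_ in emrCategories()) {
    idx <- offset + seq_along(featureNames[[cat_]])
    offset <- offset + length(featureNames[[cat_]])
    m <- colMeans(raw[, idx, drop = FALSE], na.rm = TRUE)
    s <- apply(raw[, idx, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    m[is.nan(m)] <- 0
    s[is.na(s)] <- 0
    statsList[[cat_]] <- data.frame(name = featureNames[[cat_]],
                                    mean = unname(m), sd = unname(s),
                                    stringsAsFactors = FALSE)
  }
  new("EMRFeatureSchema", categories = emrCategories(), vocab = vocab,
      featureNames = featureNames, stats = statsList,
      icdMinFrequency = icdMinFrequency, nTrain = length(train))
}

#' Transform one study into a normalised EMR feature vector
#'
#' Applies the frozen schema: category encoders with training
#' vocabularies, then z-normalisation with training mean and SD. Features
#' with zero training SD are centered only; missing raw values become 0
#' after centering (the training mean). `transformEMR` is a pure function
#' of (study, schema).
#'
#' @param study A [SyntheticStudy-class].
#' @param schema An [EMRFeatureSchema-class] from [fitEMRSchema()].
#' @param icdGroupFun Code-to-group map; must match the one used at fit.
#' @return Named numeric vector with a `categorySlices` attribute mapping
#'   each category to its index range.
#' @export
transformEMR <- function(study, schema, icdGroupFun = icdTopLevelGroup) {
  stopifnot(is(schema, "EMRFeatureSchema"))
  raw <- .encodeStudyRaw(study, schema@vocab, icdGroupFun,
                         warnUnknown = FALSE)
  out <- numeric(length(raw))
  names(out) <- names(raw)
  offset <- 0L
  slices <- list()
  for (cat_ in schema@categories) {
    st <- schema@stats[[cat_]]
    idx <- offset + seq_len(nrow(st))
    offset <- offset + nrow(st)
    slices[[cat_]] <- if (length(idx)) range(idx) else integer(0)
    x <- raw[idx] - st$mean
    scale <- ifelse(st$sd > 1e-12, st$sd, 1)
    x <- x / scale
    x[is.na(x)] <- 0   # imputed to the training mean
    out[idx] <- x
  }
  attr(out, "categorySlices") <- slices
  out
}

#' Normalised EMR feature matrix for a cohort
#'
#' @param cohort A [PECohort-class].
#' @param schema An [EMRFeatureSchema-class].
#' @param split Optional split filter ("train", "validation", "test").
#' @param icdGroupFun Code-to-group map; must match the one used at fit.
#' @return Numeric matrix (studies x features) with study ids as row
#'   names and a `categorySlices` attribute.
#' @export
emrFeatureMatrix <- function(cohort, schema, split = NULL,
                             icdGroupFun = icdTopLevelGroup) {
  studies <- if (is.null(split)) cohort@studies
             else cohortSubset(cohort, split)@studies
  vecs <- lapply(studies, transformEMR, schema = schema,
                 icdGroupFun = icdGroupFun)
  m <- do.call(rbind, vecs)
  rownames(m) <- vapply(studies, function(s) s@studyId, character(1))
  attr(m, "categorySlices") <- attr(vecs[[1]], "categorySlices")
  m
}
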