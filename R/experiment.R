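# End-to-end orchestration: trains the imaging model, the EMR-only
# models, and all seven fusion architectures on one cohort, producing
# per-split PredictionSets ready for the evaluation module.

.splitLabels <- function(cohort, split) {
  sub <- cohortSubset(cohort, split)
  labels(sub)
}

# out-of-fold probabilities on the training split (used for the stacked
# meta learner's training inputs)
.oofProbs <- function(x, y, k = 5L, seed = 1L, fitFun, predictFun) {
  set.seed(seed)
  n <- nrow(x)
  fold <- sample(rep_len(seq_len(k), n))
  out <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next   # degenerate fold: leave base rate
    fit <- fitFun(x[tr, , drop = FALSE], y[tr])
    out[!tr] <- predictFun(fit, x[!tr, , drop = FALSE])
  }
  stats::setNames(out, rownames(x))
}

#' Run the full multimodal fusion experiment on a cohort
#'
#' Trains the imaging window classifier, the six EMR-only neural networks
#' (five per-category models and one over all categories), the EMR
#' ElasticNet, and the seven fusion architectures, and returns per-split
#' prediction sets for every model. The imaging branch is frozen before
#' any fusion training: fusion models consume its predicted probabilities
#' and last-FC feature representations. The late-meta stacker is trained
#' on out-of-fold training-split probabilities for the EMR-side
#' components (the frozen imaging model contributes its ordinary
#' training-split predictions).
#'
#' @param cohort A [PECohort-class] with non-empty train/validation/test
#'   splits.
#' @param targetSize Spatial size of the preprocessed slices.
#' @param imagingConfig [imagingModelConfig()] of the CNN.
#' @param imagingEpochs,imagingBatchSize,imagingLearningRate CNN training
#'   protocol.
#' @param ffnnCfg [ffnnConfig()] shared by the feed-forward models.
#' @param ffnnEpochs,ffnnBatchSize Feed-forward training protocol.
#' @param trainImaging Set to `FALSE` to skip CNN training and use a
#'   constant base-rate imaging prediction (EMR-only ablations).
#' @param seed Master seed; all component seeds derive from it.
#' @return List with `predictions` (per split: named list of
#'   [PredictionSet-class]), `labels` and `extent` (named, per split),
#'   `imagingFit`, `schema`, `fits`.
#' @export
runFusionExperiment <- function(cohort,
                                targetSize = 32L,
                                imagingConfig = imagingModelConfig(),
                                imagingEpochs = 16L,
                                imagingBatchSize = 8L,
                                imagingLearningRate = 3e-3,
                                ffnnCfg = ffnnConfig(),
                                ffnnEpochs = 80L,
                                ffnnBatchSize = 64L,
                                trainImaging = TRUE,
                                seed = 1L) {
  splitsAll <- c("train", "validation", "test")
  y <- lapply(stats::setNames(splitsAll, splitsAll),
              function(s) .splitLabels(cohort, s))
  ext <- peExtent(cohort)
  extent <- lapply(y, function(yy) ext[names(yy)])

  # --- imaging branch (trained on overlapping windows, frozen after) ---
  imagingFit <- NULL
  imgPreds <- list(); imgFeat <- list()
  if (trainImaging) {
    trainWin <- cohortWindows(cohort, "train", targetSize, stride = 12L)
    imagingFit <- trainImagingModel(trainWin, config = imagingConfig,
                                    epochs = imagingEpochs,
                                    batchSize = imagingBatchSize,
                                    learningRate = imagingLearningRate,
                                    seed = seed)
    for (s in splitsAll) {
      infWin <- cohortWindows(cohort, s, targetSize, stride = 24L)
      pr <- predictCohortImaging(imagingFit, infWin, split = s)
      imgPreds[[s]] <- pr$predictions
      imgFeat[[s]] <- pr$features
    }
  } else {
    base <- mean(y$train)
    fDim <- imagingConfig$featureDim
    for (s in splitsAll) {
      ids <- names(y[[s]])
      imgPreds[[s]] <- predictionSet(rep(base, length(ids)),
                                     modelName = "imaging", split = s,
                                     studyIds = ids)
      imgFeat[[s]] <- matrix(0, length(ids), fDim,
                             dimnames = list(ids, NULL))
    }
  }

  # --- EMR branch -----------------------------------------------------
  schema <- fitEMRSchema(cohort)
  emr <- lapply(stats::setNames(splitsAll, splitsAll),
                function(s) emrFeatureMatrix(cohort, schema, split = s))
  slices <- attr(emr$train, "categorySlices")
  catCols <- lapply(slices, function(r) r[1]:r[2])

  preds <- lapply(stats::setNames(splitsAll, splitsAll), function(s) list())
  addPred <- function(name, probsBySplit) {
    for (s in splitsAll)
      preds[[s]][[name]] <<- predictionSet(probsBySplit[[s]],
                                           modelName = name, split = s,
                                           studyIds = names(y[[s]]))
  }
  for (s in splitsAll)
    preds[[s]][["imaging"]] <- imgPreds[[s]]

  fits <- list(imaging = imagingFit)

  # all-EMR feed-forward network
  nnAll <- trainFFNN(emr$train, y$train, config = ffnnCfg,
                     epochs = ffnnEpochs, batchSize = ffnnBatchSize,
                     xVal = emr$validation, yVal = y$validation,
                     seed = seed + 101L)
  fits$emr_nn <- nnAll
  addPred("emr_nn", lapply(emr, function(m) predict(nnAll, m)))

  # per-category feed-forward networks
  for (cat_ in emrCategories()) {
    cols <- catCols[[cat_]]
    fit <- trainFFNN(emr$train[, cols, drop = FALSE], y$train,
                     config = ffnnCfg, epochs = ffnnEpochs,
                     batchSize = ffnnBatchSize,
                     xVal = emr$validation[, cols, drop = FALSE],
                     yVal = y$validation,
                     seed = seed + 200L + match(cat_, emrCategories()))
    fits[[paste0("emr_", cat_)]] <- fit
    addPred(paste0("emr_", cat_),
            lapply(emr, function(m) predict(fit, m[, cols, drop = FALSE])))
  }

  # EMR ElasticNet
  en <- fitElasticNetEMR(emr$train, y$train, seed = seed + 301L)
  fits$emr_elasticnet <- en
  addPred("emr_elasticnet", lapply(emr, function(m) predict(en, m)))

  # --- fusion architectures -------------------------------------------
  # early fusion: EMR features + imaging last-FC features
  early <- buildEarlyFusion(ncol(emr$train), ncol(imgFeat$train),
                            config = ffnnCfg, seed = seed + 401L)
  earlyFit <- trainEarlyFusion(early, emr$train, imgFeat$train, y$train,
                               emrVal = emr$validation,
                               imageFeatVal = imgFeat$validation,
                               labelsVal = y$validation,
                               epochs = ffnnEpochs,
                               batchSize = ffnnBatchSize,
                               seed = seed + 402L)
  fits$early_fusion <- earlyFit
  addPred("early_fusion", lapply(splitsAll, function(s)
    predict(earlyFit, cbind(emr[[s]], imgFeat[[s]]))) |>
      stats::setNames(splitsAll))

  # joint fusion (all / separate)
  catDims <- vapply(catCols, length, integer(1))
  for (mode in c("all", "separate")) {
    jm <- buildJointFusion(mode, catDims, ncol(imgFeat$train),
                           extractorConfig = ffnnConfig(nHidden = 0L),
                           headConfig = ffnnCfg,
                           seed = seed + 501L + (mode == "separate"))
    jf <- trainJointFusion(jm, emr$train, imgFeat$train, y$train,
                           emrVal = emr$validation,
                           imageFeatVal = imgFeat$validation,
                           labelsVal = y$validation,
                           epochs = ffnnEpochs, batchSize = ffnnBatchSize,
                           seed = seed + 503L + (mode == "separate"))
    nm <- paste0("joint_", mode)
    fits[[nm]] <- jf
    addPred(nm, lapply(splitsAll, function(s)
      predict(jf, emr[[s]], imgFeat[[s]])) |> stats::setNames(splitsAll))
  }

  # late averages
  for (s in splitsAll) {
    preds[[s]][["late_nn_average"]] <-
      lateAverage(list(preds[[s]][["imaging"]], preds[[s]][["emr_nn"]]),
                  modelName = "late_nn_average")
    preds[[s]][["late_elastic_average"]] <-
      lateAverage(list(preds[[s]][["imaging"]],
                       preds[[s]][["emr_elasticnet"]]),
                  modelName = "late_elastic_average")
    sep <- c(list(preds[[s]][["imaging"]]),
             lapply(emrCategories(), function(cat_)
               preds[[s]][[paste0("emr_", cat_)]]),
             list(preds[[s]][["emr_nn"]]))
    preds[[s]][["late_separate_average"]] <-
      lateAverage(sep, modelName = "late_separate_average")
  }

  # late meta: stack the 7 single-modality components
  componentNames <- c("imaging", paste0("emr_", emrCategories()), "emr_nn")
  oof <- list()
  oof[["imaging"]] <- probabilities(preds$train[["imaging"]])
  for (cat_ in emrCategories()) {
    cols <- catCols[[cat_]]
    oof[[paste0("emr_", cat_)]] <- .oofProbs(
      emr$train[, cols, drop = FALSE], y$train, seed = seed + 601L,
      fitFun = function(xtr, ytr)
        trainFFNN(xtr, ytr, config = ffnnCfg,
                  epochs = max(20L, ffnnEpochs %/% 2L),
                  batchSize = ffnnBatchSize, seed = seed + 602L),
      predictFun = function(fit, xte) predict(fit, xte))
  }
  oof[["emr_nn"]] <- .oofProbs(
    emr$train, y$train, seed = seed + 603L,
    fitFun = function(xtr, ytr)
      trainFFNN(xtr, ytr, config = ffnnCfg,
                epochs = max(20L, ffnnEpochs %/% 2L),
                batchSize = ffnnBatchSize, seed = seed + 604L),
    predictFun = function(fit, xte) predict(fit, xte))
  metaTrainSets <- lapply(componentNames, function(nm)
    predictionSet(oof[[nm]], modelName = nm, split = "train"))
  metaValSets <- lapply(componentNames, function(nm)
    preds$validation[[nm]])
  meta <- trainLateMeta(metaTrainSets, y$train, config = ffnnCfg,
                        valSets = metaValSets, valLabels = y$validation,
                        epochs = ffnnEpochs, batchSize = ffnnBatchSize,
                        seed = seed + 701L)
  fits$late_meta <- meta
  for (s in splitsAll) {
    comp <- lapply(componentNames, function(nm) preds[[s]][[nm]])
    preds[[s]][["late_meta"]] <- predictionSet(
      predict(meta, comp), modelName = "late_meta", split = s,
      studyIds = comp[[1]]@studyIds)
  }

  list(predictions = preds, labels = y, extent = extent,
       imagingFit = imagingFit, schema = schema, fits = fits,
       componentNames = componentNames)
}

#' Evaluate every model of an experiment on the test split
#'
#' For each model, selects the Youden operating point on the validation
#' split and evaluates on the test split (optionally with the
#' subsegmental-excluded subgroup).
#'
#' @param experiment Result of [runFusionExperiment()].
#' @param models Model names to evaluate (default: all).
#' @param nBoot Bootstrap replicates.
#' @param subgroups Also produce the subsegmental-excluded reports.
#' @param seed Seed for the bootstrap intervals.
#' @return Named list per model: `threshold`, `report` (and
#'   `reportExcludingSubsegmental` when `subgroups = TRUE`).
#' @export
evaluateExperiment <- function(experiment, models = NULL, nBoot = 1000L,
                               subgroups = TRUE, seed = 1L) {
  preds <- experiment$predictions
  if (is.null(models)) models <- names(preds$test)
  out <- list()
  for (nm in models) {
    op <- selectOperatingPoint(preds$validation[[nm]],
                               experiment$labels$validation)
    if (subgroups) {
      rep2 <- subgroupReport(preds$test[[nm]], experiment$labels$test,
                             experiment$extent$test, op$threshold,
                             modelName = nm, nBoot = nBoot, seed = seed)
      out[[nm]] <- list(threshold = op$threshold, report = rep2$all,
                        reportExcludingSubsegmental =
                          rep2$excludingSubsegmental)
    } else {
      out[[nm]] <- list(threshold = op$threshold,
                        report = evaluateModel(preds$test[[nm]],
                                               experiment$labels$test,
                                               op$threshold,
                                               modelName = nm,
                                               nBoot = nBoot, seed = seed))
    }
  }
  out
}
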