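# The seven fusion architectures plus the single-modality EMR models.
# Early fusion: one classifier over concatenated EMR features + frozen
# imaging features. Joint fusion: trainable EMR feature extractors (one
# for all categories, or one per category) feeding a fusion head, with
# the fusion loss backpropagated into the extractors; the imaging branch
# stays frozen (precomputed last-FC features). Late fusion: unweighted
# probability averaging (NN, ElasticNet, and seven-component separate
# variants) or a stacked meta classifier over component probabilities.

#' Build an early-fusion classifier
#'
#' A single feed-forward classifier over the concatenation of all EMR
#' features with the imaging model's last-fully-connected feature
#' representation (the imaging branch is frozen).
#'
#' @param emrDim Width of the EMR feature vector.
#' @param imageFeatureDim Width of the imaging feature representation.
#' @param config An [ffnnConfig()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `early_fusion` (untrained).
#' @export
buildEarlyFusion <- function(emrDim, imageFeatureDim,
                             config = ffnnConfig(), seed = 1L) {
  stopifnot(emrDim >= 1, imageFeatureDim >= 0)
  set.seed(seed)
  inputDim <- emrDim + imageFeatureDim
  dims <- c(inputDim, rep(config$nNeurons, config$nHidden), 1L)
  structure(list(net = mlpInit(dims, config$activation, config$init),
                 inputDim = inputDim, emrDim = emrDim,
                 imageFeatureDim = imageFeatureDim, config = config),
            class = "early_fusion")
}

#' Train an early-fusion classifier
#'
#' @param model An `early_fusion` from [buildEarlyFusion()].
#' @param emr,imageFeat Training EMR feature matrix and imaging feature
#'   matrix (rows aligned by study).
#' @param labels 0/1 labels.
#' @param emrVal,imageFeatVal,labelsVal Optional validation data.
#' @param epochs,batchSize,seed Training protocol parameters.
#' @return A fitted `ffnn_fit` (see [trainFFNN()]).
#' @export
trainEarlyFusion <- function(model, emr, imageFeat, labels,
                             emrVal = NULL, imageFeatVal = NULL,
                             labelsVal = NULL, epochs = 200L,
                             batchSize = 256L, seed = 1L) {
  stopifnot(inherits(model, "early_fusion"))
  x <- cbind(emr, imageFeat)
  if (ncol(x) != model$inputDim)
    stop("feature dimension ", ncol(x),
         " does not match the model input width ", model$inputDim)
  xv <- if (!is.null(emrVal)) cbind(emrVal, imageFeatVal) else NULL
  trainFFNN(x, labels, config = model$config, epochs = epochs,
            batchSize = batchSize, xVal = xv, yVal = labelsVal,
            seed = seed, net = model$net)
}

#' Build a joint-fusion model
#'
#' `mode = "all"`: one EMR feature-extraction network over the
#' concatenated EMR vector. `mode = "separate"`: one extractor per EMR
#' category. Extractor outputs are concatenated with the (frozen) imaging
#' features and fed to a fusion head; during training the head's loss is
#' backpropagated into the extractors.
#'
#' @param mode "all" or "separate".
#' @param categoryDims Named integer vector of per-category feature
#'   widths (in concatenation order). Must be non-empty.
#' @param imageFeatureDim Width of the imaging feature representation.
#' @param extractorConfig [ffnnConfig()] shared by the extractors (its
#'   hidden layers form the extractor body).
#' @param headConfig [ffnnConfig()] of the fusion head.
#' @param extractorDim Output width of each extractor.
#' @param seed Seed for weight initialisation.
#' @return An object of class `joint_fusion` (untrained).
#' @export
buildJointFusion <- function(mode = c("all", "separate"), categoryDims,
                             imageFeatureDim,
                             extractorConfig = ffnnConfig(nHidden = 0L),
                             headConfig = ffnnConfig(),
                             extractorDim = 8L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(categoryDims) == 0)
    stop("categoryDims must name at least one EMR category")
  set.seed(seed)
  inDims <- if (mode == "all") sum(categoryDims) else categoryDims
  extractors <- lapply(inDims, function(d) {
    dims <- c(d, rep(extractorConfig$nNeurons, extractorConfig$nHidden),
              extractorDim)
    mlpInit(dims, extractorConfig$activation, extractorConfig$init,
            outActivation = "hidden")
  })
  headIn <- length(extractors) * extractorDim + imageFeatureDim
  headDims <- c(headIn, rep(headConfig$nNeurons, headConfig$nHidden), 1L)
  structure(list(mode = mode, extractors = extractors,
                 head = mlpInit(headDims, headConfig$activation,
                                headConfig$init),
                 categoryDims = categoryDims,
                 imageFeatureDim = imageFeatureDim,
                 extractorDim = as.integer(extractorDim),
                 extractorConfig = extractorConfig,
                 headConfig = headConfig, headIn = headIn),
            class = "joint_fusion")
}

.jointSlices <- function(model) {
  if (model$mode == "all") return(list(seq_len(sum(model$categoryDims))))
  ends <- cumsum(model$categoryDims)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_along(ends), function(i) starts[i]:ends[i])
}

.jointForward <- function(model, emr, imageFeat, training = FALSE) {
  slices <- .jointSlices(model)
  fw <- lapply(seq_along(model$extractors), function(j)
    mlpForward(model$extractors[[j]], emr[, slices[[j]], drop = FALSE],
               dropout = if (training) model$extractorConfig$dropout else 0,
               training = training))
  H <- do.call(cbind, lapply(fw, `[[`, "out"))
  if (!is.null(imageFeat) && model$imageFeatureDim > 0)
    H <- cbind(H, imageFeat)
  hf <- mlpForward(model$head, H,
                   dropout = if (training) model$headConfig$dropout else 0,
                   training = training)
  list(p = as.numeric(hf$out), extractorFw = fw, headFw = hf)
}

#' Train a joint-fusion model
#'
#' End-to-end gradient flow from the fusion head into the EMR extractors;
#' the imaging branch is frozen (features are precomputed inputs). When
#' `freezeExtractors = TRUE` the extractor outputs are computed once at
#' their initial weights and the head is trained on them exactly as an
#' early-fusion classifier over those features.
#'
#' @param model A `joint_fusion` from [buildJointFusion()].
#' @param emr,imageFeat Training EMR features (full concatenated matrix)
#'   and imaging features.
#' @param labels 0/1 labels.
#' @param emrVal,imageFeatVal,labelsVal Optional validation data; the
#'   returned weights are the checkpoint with the highest validation
#'   accuracy.
#' @param epochs,batchSize,seed Training protocol parameters.
#' @param freezeExtractors Freeze extractor weights (see above).
#' @return An object of class `joint_fit` with the trained model and a
#'   per-epoch history.
#' @export
trainJointFusion <- function(model, emr, imageFeat, labels,
                             emrVal = NULL, imageFeatVal = NULL,
                             labelsVal = NULL, epochs = 200L,
                             batchSize = 256L, seed = 1L,
                             freezeExtractors = FALSE) {
  stopifnot(inherits(model, "joint_fusion"))
  emr <- as.matrix(emr); y <- as.numeric(labels)
  if (freezeExtractors) {
    feats <- .jointForward(model, emr, imageFeat)$extractorFw
    H <- do.call(cbind, lapply(feats, `[[`, "out"))
    Hv <- NULL
    if (!is.null(emrVal)) {
      fv <- .jointForward(model, as.matrix(emrVal), imageFeatVal)$extractorFw
      Hv <- do.call(cbind, lapply(fv, `[[`, "out"))
      if (model$imageFeatureDim > 0) Hv <- cbind(Hv, imageFeatVal)
    }
    if (model$imageFeatureDim > 0) H <- cbind(H, imageFeat)
    fit <- trainFFNN(H, y, config = model$headConfig, epochs = epochs,
                     batchSize = batchSize, xVal = Hv, yVal = labelsVal,
                     seed = seed, net = model$head)
    model$head <- fit$net
    return(structure(list(model = model, history = fit$history,
                          bestEpoch = fit$bestEpoch, frozen = TRUE),
                     class = "joint_fit"))
  }
  set.seed(seed)
  nets <- c(model$extractors, list(model$head))
  opts <- lapply(nets, function(nt)
    optimInit(.netParams(nt), model$headConfig$optimizer,
              model$headConfig$learningRate))
  n <- nrow(emr)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, model = model)
  nExt <- length(model$extractors)
  eDim <- model$extractorDim
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1, n)]
      fw <- .jointForward(model, emr[idx, , drop = FALSE],
                          imageFeat[idx, , drop = FALSE], training = TRUE)
      p <- fw$p
      losses <- c(losses, .bceLoss(p, y[idx]))
      dZ <- matrix((p - y[idx]) / length(idx), ncol = 1)
      grH <- mlpBackward(model$head, fw$headFw$cache, dZLast = dZ)
      stepH <- optimStep(opts[[nExt + 1]], .netParams(model$head),
                         c(grH$dW, grH$db))
      opts[[nExt + 1]] <- stepH$state
      for (j in seq_len(nExt)) {
        cols <- (j - 1) * eDim + seq_len(eDim)
        dOut <- grH$dX[, cols, drop = FALSE]
        grE <- mlpBackward(model$extractors[[j]],
                           fw$extractorFw[[j]]$cache, dOut = dOut)
        stepE <- optimStep(opts[[j]], .netParams(model$extractors[[j]]),
                           c(grE$dW, grE$db))
        opts[[j]] <- stepE$state
        model$extractors[[j]] <- .netSetParams(model$extractors[[j]],
                                               stepE$params)
      }
      model$head <- .netSetParams(model$head, stepH$params)
    }
    valLoss <- NA_real_; valAcc <- NA_real_
    if (!is.null(emrVal)) {
      pv <- .jointForward(model, as.matrix(emrVal), imageFeatVal)$p
      valLoss <- .bceLoss(pv, labelsVal)
      valAcc <- mean((pv >= 0.5) == (labelsVal == 1))
      if (valAcc > best$acc)
        best <- list(acc = valAcc, epoch = ep, model = model)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = valLoss, val_acc = valAcc))
  }
  if (is.null(emrVal)) best <- list(acc = NA, epoch = epochs, model = model)
  structure(list(model = best$model, history = hist,
                 bestEpoch = best$epoch, frozen = FALSE),
            class = "joint_fit")
}

#' @describeIn trainJointFusion Predict fused probabilities.
#' @param object A `joint_fit`.
#' @param ... Unused.
#' @export
predict.joint_fit <- function(object, emr, imageFeat, ...) {
  if (isTRUE(object$frozen)) {
    fw <- .jointForward(object$model, as.matrix(emr), imageFeat)
    return(stats::setNames(fw$p, rownames(emr)))
  }
  p <- .jointForward(object$model, as.matrix(emr), imageFeat)$p
  stats::setNames(p, rownames(emr))
}

#' Unweighted late-fusion average of prediction sets
#'
#' Per-study arithmetic mean of the predicted probabilities of two or
#' more component models. Instantiates Late NN Average (imaging + all-EMR
#' NN), Late Elastic Average (imaging + EMR ElasticNet) and Late Separate
#' Average (imaging + the five per-category EMR NNs + the all-EMR NN).
#'
#' @param predictionSets List of [PredictionSet-class] covering identical
#'   study ids.
#' @param modelName Name recorded in the returned set.
#' @return A [PredictionSet-class]. The averaged probability of every
#'   study lies within the min and max of its inputs.
#' @export
lateAverage <- function(predictionSets, modelName = NULL) {
  if (length(predictionSets) == 0)
    stop("at least one prediction set required")
  ids <- predictionSets[[1]]@studyIds
  for (ps in predictionSets)
    if (!setequal(ps@studyIds, ids))
      stop("prediction sets must cover identical study ids")
  mat <- vapply(predictionSets, function(ps) probabilities(ps)[ids],
                numeric(length(ids)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(ids))
  if (is.null(modelName))
    modelName <- paste0("late_average(",
                        paste(vapply(predictionSets, function(p)
                          p@modelName, character(1)), collapse = "+"), ")")
  predictionSet(rowMeans(mat), modelName = modelName,
                split = predictionSets[[1]]@split, studyIds = ids)
}

#' Train a late-meta (stacked) fusion classifier
#'
#' A meta feed-forward classifier over the component models' predicted
#' probabilities (one input per component model).
#'
#' @param predictionSets List of at least two component
#'   [PredictionSet-class] on the training studies.
#' @param labels Named 0/1 labels covering the same study ids.
#' @param config Meta-network [ffnnConfig()].
#' @param valSets,valLabels Optional validation component sets/labels.
#' @param epochs,batchSize,seed Training protocol parameters.
#' @return An object of class `late_meta_fit`.
#' @export
trainLateMeta <- function(predictionSets, labels, config = ffnnConfig(),
                          valSets = NULL, valLabels = NULL,
                          epochs = 200L, batchSize = 256L, seed = 1L) {
  if (length(predictionSets) < 2)
    stop("late meta fusion needs at least two component prediction sets")
  ids <- predictionSets[[1]]@studyIds
  X <- vapply(predictionSets, function(ps) probabilities(ps)[ids],
              numeric(length(ids)))
  rownames(X) <- ids
  Xv <- NULL
  if (!is.null(valSets)) {
    vids <- valSets[[1]]@studyIds
    Xv <- vapply(valSets, function(ps) probabilities(ps)[vids],
                 numeric(length(vids)))
    rownames(Xv) <- vids
  }
  fit <- trainFFNN(X, labels[ids], config = config, epochs = epochs,
                   batchSize = batchSize, xVal = Xv,
                   yVal = if (!is.null(valLabels)) valLabels[rownames(Xv)],
                   seed = seed)
  structure(list(fit = fit,
                 componentNames = vapply(predictionSets, function(p)
                   p@modelName, character(1))),
            class = "late_meta_fit")
}

#' @describeIn trainLateMeta Predict fused probabilities from component
#'   prediction sets.
#' @param object A `late_meta_fit`.
#' @param ... Unused.
#' @export
predict.late_meta_fit <- function(object, predictionSets, ...) {
  ids <- predictionSets[[1]]@studyIds
  X <- vapply(predictionSets, function(ps) probabilities(ps)[ids],
              numeric(length(ids)))
  rownames(X) <- ids
  predict(object$fit, X)
}

#' Fit an ElasticNet on the EMR features
#'
#' Logistic-link linear model with combined L1/L2 penalty over the
#' normalised EMR feature matrix. Penalty strength is selected by
#' cross-validated deviance (log-loss) on the training split over a grid
#' of L1/L2 mixing values.
#'
#' @param x Normalised EMR feature matrix (training split).
#' @param y 0/1 labels.
#' @param alphaGrid L1/L2 mixing values to search (1 = lasso, 0 = ridge).
#' @param nfolds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return An object of class `elastic_emr`.
#' @export
fitElasticNetEMR <- function(x, y, alphaGrid = seq(0.1, 0.9, by = 0.1),
                             nfolds = 5L, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  best <- NULL
  for (a in alphaGrid) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = a,
                            foldid = foldid, type.measure = "deviance")
    cvm <- min(cv$cvm)
    if (is.null(best) || cvm < best$cvm)
      best <- list(cv = cv, alpha = a, cvm = cvm,
                   lambda = cv$lambda.min)
  }
  structure(list(fit = best$cv$glmnet.fit, alpha = best$alpha,
                 lambda = best$lambda, cvDeviance = best$cvm),
            class = "elastic_emr")
}

#' @describeIn fitElasticNetEMR Predict probabilities.
#' @param object An `elastic_emr`.
#' @param ... Unused.
#' @export
predict.elastic_emr <- function(object, x, ...) {
  p <- as.numeric(stats::predict(object$fit, newx = as.matrix(x),
                                 s = object$lambda, type = "response"))
  if (!is.null(rownames(x))) names(p) <- rownames(x)
  p
}
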