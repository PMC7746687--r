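mkPredSet <- function(p, ids = paste0("S", seq_along(p)), name = "m",
                      split = "test") {
  predictionSet(p, modelName = name, split = split, studyIds = ids)
}

test_that("early fusion concatenation arithmetic and dimension checks", {
  m <- buildEarlyFusion(50, 64, ffnnConfig(nHidden = 2L, nNeurons = 16L))
  expect_equal(m$inputDim, 114)
  expect_equal(m$net$dims[1], 114)
  emr <- matrix(rnorm(10 * 40), 10)   # wrong width
  img <- matrix(rnorm(10 * 64), 10)
  expect_error(trainEarlyFusion(m, emr, img, rbinom(10, 1, 0.5),
                                epochs = 1L), "does not match")
  m0 <- buildEarlyFusion(5, 0, ffnnConfig(nHidden = 0L))
  expect_length(m0$net$W, 1L)  # degenerate depth: logistic-equivalent
})

test_that("joint fusion builds one extractor per mode and sizes its head", {
  dims6 <- setNames(rep(8L, 6), paste0("c", 1:6))
  js <- buildJointFusion("separate", dims6, 64, extractorDim = 8L)
  expect_length(js$extractors, 6L)
  expect_equal(js$headIn, 6 * 8 + 64)  # (8 x 6) + 64 = 112
  ja <- buildJointFusion("all", dims6, 64, extractorDim = 8L)
  expect_length(ja$extractors, 1L)
  expect_error(buildJointFusion("all", integer(0), 64), "at least one")
})

test_that("joint fusion trains end-to-end and moves its extractors", {
  set.seed(21)
  n <- 80
  emr <- matrix(rnorm(n * 10), n,
                dimnames = list(paste0("S", 1:n), NULL))
  img <- matrix(rnorm(n * 4), n)
  y <- as.integer(emr[, 1] + rnorm(n, sd = 0.5) > 0)
  jm <- buildJointFusion("separate", c(a = 5L, b = 5L), 4L,
                         headConfig = ffnnConfig(learningRate = 0.05),
                         seed = 1L)
  w0 <- jm$extractors[[1]]$W[[1]]
  jf <- trainJointFusion(jm, emr, img, y, epochs = 30L, batchSize = 32L,
                         seed = 2L)
  expect_false(isTRUE(all.equal(jf$model$extractors[[1]]$W[[1]], w0)))
  p <- predict(jf, emr, img)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auroc(p, y), 0.8)
})

test_that("freezing the extractors reduces joint to early fusion on their features", {
  set.seed(23)
  n <- 40
  emr <- matrix(rnorm(n * 8), n, dimnames = list(paste0("S", 1:n), NULL))
  img <- matrix(rnorm(n * 3), n)
  y <- rbinom(n, 1, 0.5)
  jm <- buildJointFusion("all", c(all = 8L), 3L, extractorDim = 4L,
                         seed = 5L)
  jf <- trainJointFusion(jm, emr, img, y, epochs = 5L, batchSize = 16L,
                         seed = 6L, freezeExtractors = TRUE)
  # manual path: extractor features at initial weights + head trained as FFNN
  feats <- fusePE:::mlpForward(jm$extractors[[1]], emr)$out
  ref <- trainFFNN(cbind(feats, img), y, config = jm$headConfig,
                   epochs = 5L, batchSize = 16L, seed = 6L,
                   net = jm$head)
  expect_equal(unname(predict(jf, emr, img)),
               unname(predict(ref, cbind(feats, img))))
})

test_that("late averaging is the per-study unweighted mean", {
  a <- mkPredSet(c(0.6, 0.2), name = "A")
  b <- mkPredSet(c(0.8, 0.4), name = "B")
  avg <- lateAverage(list(a, b))
  expect_equal(unname(probabilities(avg)), c(0.7, 0.3))
  # idempotence on identical sets
  expect_equal(probabilities(lateAverage(list(a, a))), probabilities(a))
  # 7 sets: six at 0.5, one at 1.0
  sets7 <- c(lapply(1:6, function(i) mkPredSet(c(0.5, 0.5))),
             list(mkPredSet(c(1.0, 1.0))))
  expect_equal(unname(probabilities(lateAverage(sets7))[1]), 4 / 7)
  # misaligned ids and empty lists are errors
  cset <- mkPredSet(c(0.1, 0.2), ids = c("S1", "S9"))
  expect_error(lateAverage(list(a, cset)), "identical study ids")
  expect_error(lateAverage(list()), "at least one")
})

test_that("averaged probabilities stay within the envelope of the inputs", {
  set.seed(29)
  sets <- lapply(1:4, function(i) mkPredSet(runif(25)))
  avg <- probabilities(lateAverage(sets))
  mat <- sapply(sets, function(s) probabilities(s)[names(avg)])
  expect_true(all(avg >= apply(mat, 1, min) - 1e-12))
  expect_true(all(avg <= apply(mat, 1, max) + 1e-12))
})

test_that("late average degrades gracefully to the informative component", {
  set.seed(31)
  y <- rbinom(60, 1, 0.5)
  ids <- paste0("S", 1:60)
  informative <- mkPredSet(plogis(2 * (y - 0.5) + rnorm(60)), ids = ids)
  baseRate <- mkPredSet(rep(mean(y), 60), ids = ids)
  avg <- lateAverage(list(informative, baseRate))
  expect_equal(auroc(probabilities(avg)[ids], y),
               auroc(probabilities(informative)[ids], y))
})

test_that("the late meta stacker learns from component probabilities", {
  set.seed(37)
  y <- rbinom(100, 1, 0.5)
  ids <- paste0("S", 1:100)
  labs <- setNames(y, ids)
  perfect <- mkPredSet(ifelse(y == 1, 0.9, 0.1), ids = ids, split = "train")
  noise <- mkPredSet(runif(100), ids = ids, split = "train")
  expect_error(trainLateMeta(list(perfect), labs), "at least two")
  meta <- trainLateMeta(list(perfect, noise), labs,
                        config = ffnnConfig(learningRate = 0.05),
                        epochs = 60L, batchSize = 64L, seed = 1L)
  p <- predict(meta, list(perfect, noise))
  expect_equal(auroc(p, y), 1)
  # all-constant components carry no signal
  flat <- mkPredSet(rep(0.5, 100), ids = ids, split = "train")
  meta2 <- trainLateMeta(list(flat, flat), labs, epochs = 20L, seed = 2L)
  p2 <- predict(meta2, list(flat, flat))
  # constant inputs give constant output: AUROC 0.5 by complete ties
  expect_equal(length(unique(round(p2, 10))), 1L)
  expect_equal(auroc(p2, y), 0.5)
})

test_that("a linear meta model weights the informative component higher", {
  set.seed(41)
  y <- rbinom(300, 1, 0.5)
  ids <- paste0("S", 1:300)
  labs <- setNames(y, ids)
  good <- mkPredSet(plogis(3 * (y - 0.5) + rnorm(300, sd = 0.5)),
                    ids = ids, split = "train")
  weak <- mkPredSet(plogis(0.2 * (y - 0.5) + rnorm(300)),
                    ids = ids, split = "train")
  meta <- trainLateMeta(list(good, weak), labs,
                        config = ffnnConfig(nHidden = 0L,
                                            learningRate = 0.05),
                        epochs = 120L, batchSize = 256L, seed = 1L)
  w <- abs(as.numeric(meta$fit$net$W[[1]]))
  expect_gt(w[1], w[2])
})

test_that("the ElasticNet behaves across its penalty limits", {
  set.seed(43)
  n <- 150
  x <- matrix(rnorm(n * 6), n,
              dimnames = list(paste0("S", 1:n), paste0("f", 1:6)))
  y <- as.integer(x[, 1] - x[, 2] + rnorm(n, sd = 0.4) > 0)

  # pure-noise features: cross-validation picks a strong penalty and the
  # model falls back towards the base rate
  yn <- rbinom(n, 1, 0.35)
  fitNoise <- fitElasticNetEMR(x, yn, seed = 1L)
  pn <- predict(fitNoise, x)
  expect_lt(sd(pn), 0.08)
  expect_lt(abs(mean(pn) - mean(yn)), 0.1)

  # weak penalty recovers the unregularised logistic direction
  fit <- fitElasticNetEMR(x, y, seed = 2L)
  coefSmall <- as.numeric(coef(fit$fit, s = min(fit$fit$lambda)))[-1]
  ref <- coef(glm(y ~ x, family = binomial))[-1]
  cosSim <- sum(coefSmall * ref) / sqrt(sum(coefSmall^2) * sum(ref^2))
  expect_gt(cosSim, 0.98)

  # pure L2 on duplicated columns shares the weight equally
  xd <- cbind(x[, 1], x[, 1], x[, 3:6])
  colnames(xd) <- paste0("g", 1:6)
  fitR <- fitElasticNetEMR(xd, y, alphaGrid = 0, seed = 3L)
  cf <- as.numeric(coef(fitR$fit, s = fitR$lambda))[-1]
  expect_equal(cf[1], cf[2], tolerance = 1e-2)
})
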