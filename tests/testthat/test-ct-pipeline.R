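test_that("HU clipping respects the working range and is idempotent", {
  x <- c(-2000, -1000, -50, 899, 900, 2000)
  expect_equal(clipHU(x), c(-1000, -1000, -50, 899, 900, 900))
  set.seed(1)
  r <- rnorm(1000, sd = 1500)
  expect_identical(clipHU(clipHU(r)), clipHU(r))
})

test_that("preprocessing clips, resizes and zero-centers", {
  vol <- array(0, c(10, 10, 24))
  vol[1, 1, 1] <- 2000    # clipped to 900
  vol[2, 2, 1] <- -2000   # clipped to -1000
  pv <- preprocessVolume(vol, targetSize = 10L, center = -50)
  expect_equal(max(pv@voxels), 900 - (-50))
  expect_equal(min(pv@voxels), -1000 - (-50))
  # pre-normalisation range contract: voxels + center within [-1000, 900]
  expect_true(all(pv@voxels + (-50) >= -1000 & pv@voxels + (-50) <= 900))

  flat <- array(-50, c(8, 8, 24))
  pv2 <- preprocessVolume(flat, targetSize = 8L)
  expect_true(all(pv2@voxels == 0))

  pv3 <- preprocessVolume(array(0, c(9, 9, 24)), targetSize = 16L)
  expect_equal(dim(pv3@voxels)[1:2], c(16L, 16L))

  expect_error(preprocessVolume(array(NA_real_, c(4, 4, 4))), "non-finite")
  expect_error(preprocessVolume(matrix(0, 4, 4)), "3-D")
})

test_that("window labels apply the strict >35% rule", {
  mkVol <- function(nPos) {
    labs <- c(rep(1L, nPos), rep(0L, 24 - nPos))
    preprocessVolume(array(0, c(8, 8, 24)), sliceLabels = labs,
                     targetSize = 8L)
  }
  expect_equal(makeWindows(mkVol(9))@windowLabels, 1L)   # 37.5% > 35%
  expect_equal(makeWindows(mkVol(8))@windowLabels, 0L)   # 33.3% <= 35%
  expect_equal(makeWindows(mkVol(0))@windowLabels, 0L)
})

test_that("windows cover all slices at any stride", {
  pv <- preprocessVolume(array(0, c(8, 8, 50)),
                         sliceLabels = integer(50), targetSize = 8L)
  for (stride in c(5L, 12L, 24L)) {
    wb <- makeWindows(pv, stride = stride)
    covered <- sort(unique(unlist(lapply(wb@starts, function(s) s:(s + 23)))))
    expect_identical(covered, 1:50)
    expect_true(all(wb@starts + 23 <= 50))
  }
})

test_that("short volumes are reflect-padded with a warning", {
  pv <- preprocessVolume(array(0, c(8, 8, 10)),
                         sliceLabels = c(rep(1L, 5), rep(0L, 5)),
                         targetSize = 8L)
  expect_warning(wb <- makeWindows(pv), "reflect-padding")
  expect_equal(dim(wb@voxels)[3], 24L)
  expect_length(wb@starts, 1L)
})

test_that("adding a positive slice never flips a window to negative", {
  set.seed(5)
  for (rep_ in 1:50) {
    labs <- as.integer(runif(24) < runif(1))
    pv <- preprocessVolume(array(0, c(8, 8, 24)), sliceLabels = labs,
                           targetSize = 8L)
    before <- makeWindows(pv)@windowLabels
    flip <- which(labs == 0L)
    if (length(flip) == 0) next
    labs2 <- labs; labs2[sample(flip, 1)] <- 1L
    pv2 <- preprocessVolume(array(0, c(8, 8, 24)), sliceLabels = labs2,
                            targetSize = 8L)
    after <- makeWindows(pv2)@windowLabels
    expect_gte(after, before)
  }
})

test_that("focal loss matches its closed form and limits", {
  # gamma = 0, alpha = 0.5 at p = 0.5, y = 1: 0.5 * (-ln 0.5)
  expect_equal(focalLoss(0.5, 1, gamma = 0, alpha = 0.5),
               0.5 * (-log(0.5)))
  # gamma = 0 reduces to the alpha-weighted cross-entropy exactly
  set.seed(2)
  p <- runif(200, 0.01, 0.99); y <- rbinom(200, 1, 0.5); a <- 0.7
  wce <- ifelse(y == 1, -a * log(p), -(1 - a) * log(1 - p))
  expect_lt(max(abs(focalLoss(p, y, gamma = 0, alpha = a) - wce)), 1e-12)
  # non-negativity
  expect_true(all(focalLoss(p, y, gamma = 2, alpha = 0.25) >= 0))
  # focusing: as p -> 1 with y = 1, focal vanishes faster than CE
  ps <- c(0.9, 0.99, 0.999)
  ratio <- focalLoss(ps, 1, gamma = 2, alpha = 0.5) / (0.5 * -log(ps))
  expect_true(all(diff(ratio) < 0))
  expect_lt(ratio[3], 1e-4)
})

test_that("focal loss logit gradient matches numerical differentiation", {
  set.seed(3)
  z <- rnorm(20); y <- rbinom(20, 1, 0.4)
  for (gamma in c(0, 1, 2)) {
    ana <- fusePE:::.focalGradLogit(plogis(z), y, gamma, 0.6)
    num <- vapply(seq_along(z), function(i) {
      f <- function(zi) {
        zz <- z; zz[i] <- zi
        mean(focalLoss(plogis(zz), y, gamma, 0.6))
      }
      (f(z[i] + 1e-6) - f(z[i] - 1e-6)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(ana - num)), 1e-7)
  }
})

test_that("study aggregation takes the maximum window probability", {
  set.seed(4)
  co <- smallCohort()
  idx <- which(labels(co) == 1)[1]
  st <- co[[idx]]
  pv <- preprocessVolume(st@volume, st@sliceLabels, studyId = st@studyId,
                         targetSize = 16L)
  wb <- makeWindows(pv, stride = 12L)
  tr <- cohortSubset(co, "train")
  mix <- c(which(labels(tr) == 1)[1:4], which(labels(tr) == 0)[1:4])
  fit <- trainImagingModel(cohortWindows(tr[mix], "train", 16L, 12L),
                           config = imagingModelConfig(channels = c(4L),
                                                       featureDim = 8L),
                           epochs = 2L, seed = 1L)
  res <- predictStudy(fit, wb)
  expect_equal(res$probability, max(res$windowProbs))
  expect_equal(res$argmaxStart,
               wb@starts[which.max(res$windowProbs)])
  expect_length(res$features, 8L)
  # single window: its probability is the study probability
  wb1 <- makeWindows(preprocessVolume(st@volume[, , 1:24],
                                      st@sliceLabels[1:24],
                                      targetSize = 16L), stride = 24L)
  res1 <- predictStudy(fit, wb1)
  expect_length(res1$windowProbs, 1L)
  expect_equal(res1$probability, unname(res1$windowProbs[1]))
})

test_that("CNN gradients agree with numerical differentiation", {
  set.seed(42)
  cfg <- imagingModelConfig(channels = c(2L, 3L), useSE = TRUE,
                            seReduction = 2L, useSkip = TRUE,
                            featureDim = 4L, inputScale = 1)
  model <- fusePE:::.cnnInit(cfg)
  model$bn$rmu <- rnorm(3); model$bn$rvar <- runif(3, 0.5, 2)
  model$bn$gamma <- runif(3, 0.5, 2); model$bn$beta <- rnorm(3)
  x <- array(rnorm(6 * 6 * 6 * 1 * 3), c(6, 6, 6, 1, 3))
  y <- c(1, 0, 1)
  for (training in c(TRUE, FALSE)) {
    lossFn <- function(m) {
      mean(focalLoss(fusePE:::.cnnForward(m, x, training = training)$p,
                     y, 2, 0.6))
    }
    fw <- fusePE:::.cnnForward(model, x, keepCache = TRUE,
                               training = training)
    dz <- matrix(fusePE:::.focalGradLogit(fw$p, y, 2, 0.6), ncol = 1)
    gr <- fusePE:::.cnnBackward(model, fw$cache, dz)
    pl <- fusePE:::.cnnParamList(model)
    gl <- fusePE:::.cnnGradList(model, gr)
    maxrel <- 0
    for (nm in names(pl)) {
      for (j in sample(seq_along(pl[[nm]]), min(3, length(pl[[nm]])))) {
        plp <- pl; plp[[nm]][j] <- plp[[nm]][j] + 1e-5
        plm <- pl; plm[[nm]][j] <- plm[[nm]][j] - 1e-5
        num <- (lossFn(fusePE:::.cnnSetParams(model, plp)) -
                  lossFn(fusePE:::.cnnSetParams(model, plm))) / 2e-5
        ana <- as.numeric(gl[[nm]])[j]
        maxrel <- max(maxrel, abs(num - ana) /
                        max(1e-6, abs(num) + abs(ana)))
      }
    }
    expect_lt(maxrel, 1e-5)
  }
})

test_that("training rejects single-class window sets", {
  co <- smallCohort()
  negIds <- names(labels(co))[labels(co) == 0][1:3]
  wins <- lapply(negIds, function(id) {
    st <- co@studies[[which(studyIds(co) == id)]]
    makeWindows(preprocessVolume(st@volume, st@sliceLabels,
                                 targetSize = 16L), stride = 24L)
  })
  expect_error(trainImagingModel(wins, epochs = 1L), "both classes")
})
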