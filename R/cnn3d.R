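# Desk-scale 3-D convolutional imaging classifier: stages of strided
# 3x3x3 convolutions with ELU activations, optional squeeze-and-excitation
# (SE) channel gating and optional 1x1x1-projection skip connections,
# followed by global average pooling, one fully connected feature layer
# and a single sigmoid output unit. Trained with a focal loss. The
# architecture family (3-D convolutions + skip connections + SE blocks +
# max-window study aggregation) mirrors large CT backbones at a size a
# single CPU can train on synthetic volumes; convolutions are evaluated
# via im2col matrix products so the heavy lifting stays in BLAS.

.convOutLen <- function(n, k, stride) {
  p <- (k - 1L) %/% 2L
  as.integer((n + 2L * p - k) %/% stride + 1L)
}

# Build the im2col matrix: rows index (oD, oH, oW, B) column-major, one
# column per (kernel offset, input channel) in the same order as
# matrix(w, k^3 * Cin, Cout).
.im2col <- function(x, k, stride) {
  dm <- dim(x)
  D <- dm[1]; H <- dm[2]; W <- dm[3]; Cin <- dm[4]; B <- dm[5]
  p <- (k - 1L) %/% 2L
  oD <- .convOutLen(D, k, stride)
  oH <- .convOutLen(H, k, stride)
  oW <- .convOutLen(W, k, stride)
  if (p > 0) {
    xp <- array(0, c(D + 2 * p, H + 2 * p, W + 2 * p, Cin, B))
    xp[p + seq_len(D), p + seq_len(H), p + seq_len(W), , ] <- x
  } else xp <- x
  iD <- seq.int(1L, by = stride, length.out = oD)
  iH <- seq.int(1L, by = stride, length.out = oH)
  iW <- seq.int(1L, by = stride, length.out = oW)
  n <- oD * oH * oW * B
  S <- matrix(0, n, k^3 * Cin)
  col <- 0L
  for (ci in seq_len(Cin)) for (cc in seq_len(k)) for (b in seq_len(k))
    for (a in seq_len(k)) {
      col <- col + 1L
      S[, col] <- xp[iD + a - 1L, iH + b - 1L, iW + cc - 1L, ci, ]
    }
  list(S = S, oD = oD, oH = oH, oW = oW, B = B, k = k, stride = stride,
       inDim = dm)
}

.conv3dForward <- function(x, w, bias, stride, keepCache = FALSE) {
  k <- dim(w)[1]; Cout <- dim(w)[5]
  ic <- .im2col(x, k, stride)
  wmat <- matrix(w, ncol = Cout)
  outMat <- ic$S %*% wmat
  outMat <- outMat + rep(bias, each = nrow(outMat))
  out <- array(0, c(ic$oD, ic$oH, ic$oW, Cout, ic$B))
  for (co in seq_len(Cout)) out[, , , co, ] <- outMat[, co]
  cache <- if (keepCache) ic else NULL
  list(out = out, cache = cache)
}

.conv3dBackward <- function(dout, w, cache) {
  k <- cache$k; stride <- cache$stride
  Cout <- dim(w)[5]
  n <- nrow(cache$S)
  Dmat <- matrix(0, n, Cout)
  for (co in seq_len(Cout)) {
    sl <- dout[, , , co, , drop = FALSE]
    Dmat[, co] <- sl
  }
  db <- colSums(Dmat)
  dwmat <- crossprod(cache$S, Dmat)
  dw <- array(dwmat, dim = dim(w))
  # scatter dS back to the (padded) input grid
  dS <- tcrossprod(Dmat, matrix(w, ncol = Cout))
  dm <- cache$inDim
  D <- dm[1]; H <- dm[2]; W <- dm[3]; Cin <- dm[4]; B <- dm[5]
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(D + 2 * p, H + 2 * p, W + 2 * p, Cin, B))
  iD <- seq.int(1L, by = stride, length.out = cache$oD)
  iH <- seq.int(1L, by = stride, length.out = cache$oH)
  iW <- seq.int(1L, by = stride, length.out = cache$oW)
  shp <- c(cache$oD, cache$oH, cache$oW, B)
  col <- 0L
  for (ci in seq_len(Cin)) for (cc in seq_len(k)) for (b in seq_len(k))
    for (a in seq_len(k)) {
      col <- col + 1L
      cur <- dxp[iD + a - 1L, iH + b - 1L, iW + cc - 1L, ci, , drop = FALSE]
      dim(cur) <- shp
      dxp[iD + a - 1L, iH + b - 1L, iW + cc - 1L, ci, ] <-
        cur + array(dS[, col], shp)
    }
  dx <- if (p > 0)
    dxp[p + seq_len(D), p + seq_len(H), p + seq_len(W), , , drop = FALSE]
  else dxp
  dim(dx) <- dm
  list(dx = dx, dw = dw, db = db)
}

.seForward <- function(x, se) {
  dm <- dim(x)
  npix <- prod(dm[1:3])
  s <- apply(x, c(4, 5), mean)               # [C, B]
  if (is.null(dim(s))) s <- matrix(s, dm[4], dm[5])
  z1 <- se$W1 %*% s + se$b1
  a1 <- pmax(z1, 0)
  z2 <- se$W2 %*% a1 + se$b2
  g <- stats::plogis(z2)                     # [C, B]
  garr <- array(rep(g, each = npix), dim = dm)
  list(out = x * garr, cache = list(x = x, s = s, z1 = z1, a1 = a1,
                                    g = g, garr = garr, npix = npix))
}

.seBackward <- function(dout, se, cache) {
  dm <- dim(cache$x)
  dg <- apply(dout * cache$x, c(4, 5), sum)
  if (is.null(dim(dg))) dg <- matrix(dg, dm[4], dm[5])
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(dz2, cache$a1)
  db2 <- rowSums(dz2)
  da1 <- crossprod(se$W2, dz2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- tcrossprod(dz1, cache$s)
  db1 <- rowSums(dz1)
  ds <- crossprod(se$W1, dz1)                # [C, B]
  dx <- dout * cache$garr +
    array(rep(ds / cache$npix, each = cache$npix), dim = dm)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Imaging model configuration
#'
#' Architecture of the 3-D CNN window classifier: per-stage channel
#' widths (each stage halves every spatial dimension), optional SE blocks
#' with the given channel-reduction ratio, optional projection skip
#' connections, and the width of the last fully connected representation
#' (the feature vector used by the fusion models).
#'
#' @param channels Integer vector of per-stage output channels.
#' @param useSE Include squeeze-and-excitation channel gating.
#' @param seReduction SE bottleneck reduction ratio.
#' @param useSkip Include 1x1x1-projection skip connections.
#' @param featureDim Width of the last fully connected layer.
#' @param inputScale Internal multiplicative rescaling of the
#'   zero-centered HU inputs before the first convolution (default
#'   1/475, mapping the clipped range to roughly [-2, 2] for optimiser
#'   stability; purely an implementation detail of the model).
#' @param pool Global pooling over the last stage: "mean" (default) or
#'   "max" per channel.
#' @return A list of class `imagingModelConfig`.
#' @export
imagingModelConfig <- function(channels = c(8L, 16L), useSE = TRUE,
                               seReduction = 4L, useSkip = TRUE,
                               featureDim = 32L, inputScale = 1 / 475,
                               pool = c("mean", "max")) {
  stopifnot(length(channels) >= 1, all(channels >= 1), featureDim >= 1,
            inputScale > 0)
  pool <- match.arg(pool)
  structure(list(channels = as.integer(channels), useSE = useSE,
                 seReduction = as.integer(seReduction), useSkip = useSkip,
                 featureDim = as.integer(featureDim),
                 inputScale = inputScale, pool = pool),
            class = "imagingModelConfig")
}

.cnnInit <- function(config) {
  cin <- 1L
  stages <- list()
  for (co in config$channels) {
    st <- list(
      w = array(stats::rnorm(27 * cin * co, sd = sqrt(2 / (27 * cin))),
                c(3, 3, 3, cin, co)),
      b = numeric(co))
    if (config$useSE) {
      cr <- max(1L, co %/% config$seReduction)
      st$se <- list(W1 = matrix(stats::rnorm(cr * co, sd = sqrt(2 / co)),
                                cr, co),
                    b1 = numeric(cr),
                    W2 = matrix(stats::rnorm(co * cr, sd = sqrt(2 / cr)),
                                co, cr),
                    b2 = numeric(co))
    }
    if (config$useSkip) {
      st$proj <- list(w = array(stats::rnorm(cin * co, sd = sqrt(2 / cin)),
                                c(1, 1, 1, cin, co)),
                      b = numeric(co))
    }
    stages[[length(stages) + 1]] <- st
    cin <- co
  }
  cLast <- utils::tail(config$channels, 1)
  head <- list(
    Wf = matrix(stats::rnorm(cLast * config$featureDim,
                             sd = sqrt(2 / cLast)), cLast, config$featureDim),
    bf = numeric(config$featureDim),
    Wo = matrix(stats::rnorm(config$featureDim, sd = sqrt(2 / config$featureDim)),
                config$featureDim, 1),
    bo = 0)
  bn <- list(gamma = rep(1, cLast), beta = numeric(cLast),
             rmu = numeric(cLast), rvar = rep(1, cLast),
             initialized = FALSE)
  list(config = config, stages = stages, head = head, bn = bn)
}

.cnnForward <- function(model, x, keepCache = FALSE, training = FALSE) {
  caches <- list()
  a <- x * model$config$inputScale
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    cv <- .conv3dForward(a, st$w, st$b, 2L, keepCache = keepCache)
    z <- cv$out
    y <- ifelse(z > 0, z, expm1(z))            # ELU
    dim(y) <- dim(z)
    se <- if (!is.null(st$se)) .seForward(y, st$se) else NULL
    y2 <- if (is.null(se)) y else se$out
    pj <- if (!is.null(st$proj))
      .conv3dForward(a, st$proj$w, st$proj$b, 2L, keepCache = keepCache)
    else NULL
    out <- if (is.null(pj)) y2 else y2 + pj$out
    caches[[i]] <- list(conv = cv$cache, z = z, elu = y, se = se,
                        proj = pj$cache, dimIn = dim(a))
    a <- out
  }
  dm <- dim(a)
  npix <- prod(dm[1:3])
  am <- a
  dim(am) <- c(npix, dm[4], dm[5])
  if (model$config$pool == "max") {
    pool <- apply(am, c(2, 3), max)            # [C, B]
    argmax <- apply(am, c(2, 3), which.max)
  } else {
    pool <- apply(am, c(2, 3), mean)
    argmax <- NULL
  }
  if (is.null(dim(pool))) pool <- matrix(pool, dm[4], dm[5])
  poolT <- t(pool)                             # [B, C]
  # batch normalisation of the pooled features: between-window contrasts
  # are a small fraction of the absolute pooled responses, so the head is
  # badly conditioned on raw pooled values. Batch statistics are used
  # during training, running statistics at inference.
  bn <- model$bn
  usedBatchStats <- training && nrow(poolT) > 1
  if (usedBatchStats) {
    bnMu <- colMeans(poolT)
    bnVar <- colMeans(sweep(poolT, 2, bnMu, "-")^2)
  } else {
    bnMu <- bn$rmu
    bnVar <- bn$rvar
  }
  bnIstd <- 1 / sqrt(bnVar + 1e-5)
  xhat <- sweep(sweep(poolT, 2, bnMu, "-"), 2, bnIstd, "*")
  poolBN <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  hPre <- poolBN %*% model$head$Wf + rep(model$head$bf, each = nrow(poolBN))
  h <- pmax(hPre, 0)
  zOut <- h %*% model$head$Wo + model$head$bo
  p <- as.numeric(stats::plogis(zOut))
  list(p = p, features = h, zOut = zOut,
       bnBatchStats = if (usedBatchStats) list(mu = bnMu, var = bnVar),
       cache = if (keepCache) list(stages = caches, lastDim = dm,
                                   npix = npix, poolBN = poolBN,
                                   poolRaw = poolT,
                                   xhat = xhat, bnIstd = bnIstd,
                                   usedBatchStats = usedBatchStats,
                                   hPre = hPre, h = h,
                                   argmax = argmax) else NULL)
}

# returns gradients in the same nested layout as the model parameters
.cnnBackward <- function(model, cache, dz) {
  gr <- list(stages = vector("list", length(model$stages)), head = list())
  h <- cache$h
  gr$head$Wo <- crossprod(h, dz)
  gr$head$bo <- sum(dz)
  dh <- (dz %*% t(model$head$Wo)) * (cache$hPre > 0)
  gr$head$Wf <- crossprod(cache$poolBN, dh)
  gr$head$bf <- colSums(dh)
  dpoolBN <- dh %*% t(model$head$Wf)           # [B, C]
  gr$head$bnG <- colSums(dpoolBN * cache$xhat)
  gr$head$bnB <- colSums(dpoolBN)
  dxhat <- sweep(dpoolBN, 2, model$bn$gamma, "*")
  if (cache$usedBatchStats) {
    B <- nrow(dxhat)
    mDx <- matrix(colMeans(dxhat), B, ncol(dxhat), byrow = TRUE)
    mDxX <- matrix(colMeans(dxhat * cache$xhat), B, ncol(dxhat),
                   byrow = TRUE)
    dpoolT <- sweep(dxhat - mDx - cache$xhat * mDxX, 2, cache$bnIstd, "*")
  } else {
    dpoolT <- sweep(dxhat, 2, cache$bnIstd, "*")
  }
  dm <- cache$lastDim
  if (model$config$pool == "max") {
    # route the gradient to the argmax voxel of each channel
    da <- array(0, dim = dm)
    C <- dm[4]; B <- dm[5]
    cb <- expand.grid(c = seq_len(C), b = seq_len(B))
    lin <- (cb$b - 1) * cache$npix * C + (cb$c - 1) * cache$npix +
      as.vector(cache$argmax)
    da[lin] <- t(dpoolT)
  } else {
    dpool <- t(dpoolT) / cache$npix            # [C, B]
    da <- array(rep(dpool, each = cache$npix), dim = dm)
  }
  for (i in rev(seq_along(model$stages))) {
    st <- model$stages[[i]]
    cs <- cache$stages[[i]]
    g <- list()
    dxTotal <- 0
    if (!is.null(st$proj)) {
      pb <- .conv3dBackward(da, st$proj$w, cs$proj)
      g$proj <- list(dw = pb$dw, db = pb$db)
      dxTotal <- pb$dx
    }
    dy2 <- da
    if (!is.null(st$se)) {
      sb <- .seBackward(dy2, st$se, cs$se$cache)
      g$se <- list(dW1 = sb$dW1, db1 = sb$db1, dW2 = sb$dW2, db2 = sb$db2)
      dy2 <- sb$dx
    }
    dElu <- ifelse(cs$z > 0, 1, cs$elu + 1)
    dim(dElu) <- dim(cs$z)
    dzc <- dy2 * dElu
    cb <- .conv3dBackward(dzc, st$w, cs$conv)
    g$dw <- cb$dw
    g$db <- cb$db
    gr$stages[[i]] <- g
    da <- cb$dx + dxTotal
    dim(da) <- cs$dimIn
  }
  gr
}

# flatten model parameters / gradients into aligned lists
.cnnParamList <- function(model) {
  out <- list()
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    out[[sprintf("s%d.w", i)]] <- st$w
    out[[sprintf("s%d.b", i)]] <- st$b
    if (!is.null(st$se)) {
      out[[sprintf("s%d.seW1", i)]] <- st$se$W1
      out[[sprintf("s%d.seb1", i)]] <- st$se$b1
      out[[sprintf("s%d.seW2", i)]] <- st$se$W2
      out[[sprintf("s%d.seb2", i)]] <- st$se$b2
    }
    if (!is.null(st$proj)) {
      out[[sprintf("s%d.pw", i)]] <- st$proj$w
      out[[sprintf("s%d.pb", i)]] <- st$proj$b
    }
  }
  out[["h.Wf"]] <- model$head$Wf
  out[["h.bf"]] <- model$head$bf
  out[["h.Wo"]] <- model$head$Wo
  out[["h.bo"]] <- model$head$bo
  out[["h.bnG"]] <- model$bn$gamma
  out[["h.bnB"]] <- model$bn$beta
  out
}

.cnnGradList <- function(model, gr) {
  out <- list()
  for (i in seq_along(model$stages)) {
    g <- gr$stages[[i]]
    out[[sprintf("s%d.w", i)]] <- g$dw
    out[[sprintf("s%d.b", i)]] <- g$db
    if (!is.null(model$stages[[i]]$se)) {
      out[[sprintf("s%d.seW1", i)]] <- g$se$dW1
      out[[sprintf("s%d.seb1", i)]] <- g$se$db1
      out[[sprintf("s%d.seW2", i)]] <- g$se$dW2
      out[[sprintf("s%d.seb2", i)]] <- g$se$db2
    }
    if (!is.null(model$stages[[i]]$proj)) {
      out[[sprintf("s%d.pw", i)]] <- g$proj$dw
      out[[sprintf("s%d.pb", i)]] <- g$proj$db
    }
  }
  out[["h.Wf"]] <- gr$head$Wf
  out[["h.bf"]] <- gr$head$bf
  out[["h.Wo"]] <- gr$head$Wo
  out[["h.bo"]] <- gr$head$bo
  out[["h.bnG"]] <- gr$head$bnG
  out[["h.bnB"]] <- gr$head$bnB
  out
}

.cnnSetParams <- function(model, params) {
  for (i in seq_along(model$stages)) {
    model$stages[[i]]$w <- array(params[[sprintf("s%d.w", i)]],
                                 dim = dim(model$stages[[i]]$w))
    model$stages[[i]]$b <- as.numeric(params[[sprintf("s%d.b", i)]])
    if (!is.null(model$stages[[i]]$se)) {
      se <- model$stages[[i]]$se
      se$W1 <- matrix(params[[sprintf("s%d.seW1", i)]], nrow(se$W1))
      se$b1 <- as.numeric(params[[sprintf("s%d.seb1", i)]])
      se$W2 <- matrix(params[[sprintf("s%d.seW2", i)]], nrow(se$W2))
      se$b2 <- as.numeric(params[[sprintf("s%d.seb2", i)]])
      model$stages[[i]]$se <- se
    }
    if (!is.null(model$stages[[i]]$proj)) {
      model$stages[[i]]$proj$w <- array(params[[sprintf("s%d.pw", i)]],
                                        dim = dim(model$stages[[i]]$proj$w))
      model$stages[[i]]$proj$b <- as.numeric(params[[sprintf("s%d.pb", i)]])
    }
  }
  model$head$Wf <- matrix(params[["h.Wf"]], nrow(model$head$Wf))
  model$head$bf <- as.numeric(params[["h.bf"]])
  model$head$Wo <- matrix(params[["h.Wo"]], ncol = 1)
  model$head$bo <- as.numeric(params[["h.bo"]])
  model$bn$gamma <- as.numeric(params[["h.bnG"]])
  model$bn$beta <- as.numeric(params[["h.bnB"]])
  model
}

# assemble a 5-D [slices, h, w, 1, B] batch from (batch, windowIndex) pairs
.windowTensor <- function(batches, table, rows) {
  first <- .windowArray(batches[[table$batch[rows[1]]]], table$window[rows[1]])
  dm <- dim(first)
  x <- array(0, c(dm, 1, length(rows)))
  x[, , , 1, 1] <- first
  if (length(rows) > 1) {
    for (j in 2:length(rows)) {
      r <- rows[j]
      x[, , , 1, j] <- .windowArray(batches[[table$batch[r]]],
                                    table$window[r])
    }
  }
  x
}

#' Train the imaging window classifier
#'
#' Trains the 3-D CNN on 24-slice sliding windows under a focal loss with
#' the Adam optimiser. The run is deterministic given `seed` (a fixed
#' thread policy is assumed; BLAS reductions are single-threaded in the
#' reference setup).
#'
#' @param windowBatches List of [WindowBatch-class] objects (training
#'   studies). Windows of both classes must be present.
#' @param config An [imagingModelConfig()].
#' @param gamma Focal-loss focusing exponent.
#' @param alpha Focal-loss class-balance weight; default
#'   1 - (positive window fraction), i.e. inverse class frequency.
#' @param epochs Training epochs.
#' @param batchSize Windows per mini-batch.
#' @param learningRate Adam learning rate.
#' @param valBatches Optional validation [WindowBatch-class] list; per-epoch
#'   window-level validation loss is recorded.
#' @param seed Seed controlling initialisation and shuffling.
#' @return An object of class `imaging_fit` with the trained model, the
#'   loss parameters and a per-epoch history.
#' @export
trainImagingModel <- function(windowBatches, config = imagingModelConfig(),
                              gamma = 2, alpha = NULL, epochs = 16L,
                              batchSize = 8L, learningRate = 3e-3,
                              clipNorm = 1, valBatches = NULL, seed = 1L) {
  table <- do.call(rbind, lapply(seq_along(windowBatches), function(i) {
    wb <- windowBatches[[i]]
    data.frame(batch = i, window = seq_along(wb@starts),
               label = wb@windowLabels)
  }))
  if (length(unique(table$label)) < 2)
    stop("training windows must contain both classes")
  if (is.null(alpha)) alpha <- 1 - mean(table$label)
  set.seed(seed)
  model <- .cnnInit(config)
  opt <- optimInit(.cnnParamList(model), "adam", learningRate)
  n <- nrow(table)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  valTable <- if (!is.null(valBatches))
    do.call(rbind, lapply(seq_along(valBatches), function(i) {
      wb <- valBatches[[i]]
      data.frame(batch = i, window = seq_along(wb@starts),
                 label = wb@windowLabels)
    })) else NULL
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batchSize)) {
      rows <- ord[start:min(start + batchSize - 1, n)]
      x <- .windowTensor(windowBatches, table, rows)
      y <- table$label[rows]
      fw <- .cnnForward(model, x, keepCache = TRUE, training = TRUE)
      losses <- c(losses, mean(focalLoss(fw$p, y, gamma, alpha)))
      if (!is.null(fw$bnBatchStats)) {
        bs <- fw$bnBatchStats
        if (!model$bn$initialized) {
          model$bn$rmu <- bs$mu; model$bn$rvar <- bs$var
          model$bn$initialized <- TRUE
        } else {
          model$bn$rmu <- 0.9 * model$bn$rmu + 0.1 * bs$mu
          model$bn$rvar <- 0.9 * model$bn$rvar + 0.1 * bs$var
        }
      }
      dz <- matrix(.focalGradLogit(fw$p, y, gamma, alpha), ncol = 1)
      gr <- .cnnBackward(model, fw$cache, dz)
      gl <- .cnnGradList(model, gr)
      # global gradient-norm clipping: the pooled-feature calibration can
      # rescale body gradients by large factors on low-variance channels
      gnorm <- sqrt(sum(vapply(gl, function(g) sum(as.numeric(g)^2),
                               numeric(1))))
      if (is.finite(gnorm) && gnorm > clipNorm)
        gl <- lapply(gl, function(g) g * (clipNorm / gnorm))
      step <- optimStep(opt, .cnnParamList(model), gl)
      opt <- step$state
      model <- .cnnSetParams(model, step$params)
    }
    valLoss <- NA_real_
    if (!is.null(valTable)) {
      vp <- numeric(nrow(valTable))
      for (start in seq(1, nrow(valTable), by = batchSize)) {
        rows <- start:min(start + batchSize - 1, nrow(valTable))
        x <- .windowTensor(valBatches, valTable, rows)
        vp[rows] <- .cnnForward(model, x)$p
      }
      valLoss <- mean(focalLoss(vp, valTable$label, gamma, alpha))
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = valLoss))
  }
  # recalibrate the batch-norm running statistics at the final weights:
  # pooled means drift with the weights during training, so the momentum
  # average lags far behind on low-variance channels
  raw <- NULL
  for (start in seq(1, n, by = 64L)) {
    rows <- start:min(start + 63L, n)
    x <- .windowTensor(windowBatches, table, rows)
    raw <- rbind(raw, .cnnForward(model, x, keepCache = TRUE)$cache$poolRaw)
  }
  model$bn$rmu <- colMeans(raw)
  model$bn$rvar <- apply(raw, 2, function(col) mean((col - mean(col))^2))
  structure(list(model = model, gamma = gamma, alpha = alpha,
                 history = hist, config = config),
            class = "imaging_fit")
}

#' Study-level prediction from the imaging model
#'
#' Runs every window of a study through the CNN and aggregates by the
#' maximum window probability; the study's feature representation is the
#' last-fully-connected-layer activation of the argmax window. Ties at
#' the maximum are broken deterministically towards the lowest window
#' start index.
#'
#' @param fit An `imaging_fit` from [trainImagingModel()].
#' @param windows A [WindowBatch-class] for one study.
#' @return List with `probability`, `features`, `windowProbs`,
#'   `argmaxStart`.
#' @export
predictStudy <- function(fit, windows) {
  stopifnot(is(windows, "WindowBatch"))
  nW <- length(windows@starts)
  dm <- c(windows@windowLength, dim(windows@voxels)[1],
          dim(windows@voxels)[2])
  x <- array(0, c(dm, 1, nW))
  for (i in seq_len(nW)) x[, , , 1, i] <- .windowArray(windows, i)
  fw <- .cnnForward(fit$model, x)
  best <- which.max(fw$p)    # first index on ties: lowest start wins
  list(probability = fw$p[best],
       features = as.numeric(fw$features[best, ]),
       windowProbs = stats::setNames(fw$p, windows@starts),
       argmaxStart = windows@starts[best])
}

#' Preprocess a cohort split and build its window batches
#'
#' @param cohort A [PECohort-class].
#' @param split Split name.
#' @param targetSize Spatial size passed to [preprocessVolume()].
#' @param stride Window stride (12 for training, 24 for inference).
#' @return Named list of [WindowBatch-class], keyed by study id.
#' @export
cohortWindows <- function(cohort, split, targetSize = 224L, stride = 12L) {
  studies <- cohortSubset(cohort, split)@studies
  out <- lapply(studies, function(s) {
    pv <- preprocessVolume(s@volume, s@sliceLabels, studyId = s@studyId,
                           targetSize = targetSize)
    makeWindows(pv, stride = stride)
  })
  names(out) <- vapply(studies, function(s) s@studyId, character(1))
  out
}

#' Imaging predictions and features for a cohort split
#'
#' @param fit An `imaging_fit`.
#' @param windowList Named list of [WindowBatch-class] (see
#'   [cohortWindows()]), typically built at inference stride 24.
#' @param split Split label recorded in the returned set.
#' @return List with `predictions` (a [PredictionSet-class]) and
#'   `features` (matrix of last-FC activations, rows = studies).
#' @export
predictCohortImaging <- function(fit, windowList, split = "test") {
  res <- lapply(windowList, function(wb) predictStudy(fit, wb))
  probs <- vapply(res, `[[`, numeric(1), "probability")
  feats <- do.call(rbind, lapply(res, `[[`, "features"))
  rownames(feats) <- names(windowList)
  list(predictions = predictionSet(probs, modelName = "imaging",
                                   split = split,
                                   studyIds = names(windowList)),
       features = feats)
}
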