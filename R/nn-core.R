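# Feed-forward network core used by the EMR-only and fusion models.
# Dense layers with ELU / LeakyReLU / Tanh activations, Normal / Xavier /
# Kaiming initialisation, inverted dropout, Adam / SGD / AdaDelta
# optimisers, and a sigmoid output trained under binary cross-entropy.
# All gradients are analytic and checked against numerical differentiation
# in the test suite.

.activation <- function(name) {
  switch(tolower(name),
    elu = list(
      f = function(x) ifelse(x > 0, x, expm1(x)),
      df = function(x) ifelse(x > 0, 1, exp(x))),
    leakyrelu = list(
      f = function(x) ifelse(x > 0, x, 0.01 * x),
      df = function(x) ifelse(x > 0, 1, 0.01)),
    tanh = list(
      f = tanh,
      df = function(x) 1 - tanh(x)^2),
    relu = list(
      f = function(x) pmax(x, 0),
      df = function(x) as.numeric(x > 0)),
    stop("unknown activation: ", name))
}

.initWeights <- function(fin, fout, method) {
  switch(tolower(method),
    normal = matrix(stats::rnorm(fin * fout, sd = 0.05), fin, fout),
    xavier = {
      lim <- sqrt(6 / (fin + fout))
      matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
    },
    kaiming = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout),
    stop("unknown init: ", method))
}

#' Feed-forward network configuration
#'
#' Hyperparameters of a feed-forward classifier. Values are soft-checked
#' against the canonical search ranges (activation in \{ELU, LeakyReLU,
#' Tanh\}, 0-10 hidden layers, 10-500 neurons, optimizer in \{Adam, SGD,
#' AdaDelta\}, learning rate 1e-4 to 1e-1, init in \{Normal, Xavier,
#' Kaiming\}, dropout 0.3-0.8); out-of-range values are allowed with a
#' warning.
#'
#' @param activation Hidden activation.
#' @param nHidden Number of hidden layers.
#' @param nNeurons Neurons per hidden layer.
#' @param optimizer Optimiser name.
#' @param learningRate Learning rate (ignored by AdaDelta's internal
#'   schedule beyond a global multiplier).
#' @param init Weight initialisation method.
#' @param dropout Dropout rate on hidden activations during training.
#' @return A list of class `ffnnConfig`.
#' @export
ffnnConfig <- function(activation = "ELU", nHidden = 1L, nNeurons = 32L,
                       optimizer = "Adam", learningRate = 0.01,
                       init = "Kaiming", dropout = 0.3) {
  cfg <- list(activation = activation, nHidden = as.integer(nHidden),
              nNeurons = as.integer(nNeurons), optimizer = optimizer,
              learningRate = learningRate, init = init, dropout = dropout)
  class(cfg) <- "ffnnConfig"
  if (!tolower(activation) %in% c("elu", "leakyrelu", "tanh"))
    warning("activation '", activation, "' outside the canonical range")
  if (nHidden < 0 || nHidden > 10)
    warning("nHidden outside the canonical range [0, 10]")
  if (nHidden > 0 && (nNeurons < 10 || nNeurons > 500))
    warning("nNeurons outside the canonical range [10, 500]")
  if (!tolower(optimizer) %in% c("adam", "sgd", "adadelta"))
    warning("optimizer '", optimizer, "' outside the canonical set")
  if (learningRate < 1e-4 || learningRate > 0.1)
    warning("learningRate outside the canonical range [1e-4, 0.1]")
  if (!tolower(init) %in% c("normal", "xavier", "kaiming"))
    warning("init '", init, "' outside the canonical set")
  if (dropout < 0.3 || dropout > 0.8)
    warning("dropout outside the canonical range [0.3, 0.8]")
  cfg
}

# A plain MLP: list(W, b, activation, outActivation).
# outActivation: "sigmoid" (classifier logits), "hidden" (extractor whose
# output is the activation of its last layer), or "linear".
mlpInit <- function(dims, activation, init, outActivation = "sigmoid") {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- .initWeights(dims[l], dims[l + 1], init)
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, activation = activation,
       outActivation = outActivation, dims = dims)
}

# Forward pass. x: n x d matrix. Returns list(out, cache).
mlpForward <- function(net, x, dropout = 0, training = FALSE) {
  act <- .activation(net$activation)
  L <- length(net$W)
  A <- list(x); Z <- vector("list", L); mask <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a))
    Z[[l]] <- z
    lastLayer <- l == L
    if (lastLayer && net$outActivation == "sigmoid") {
      a <- stats::plogis(z)
    } else if (lastLayer && net$outActivation == "linear") {
      a <- z
    } else {
      a <- act$f(z)
      if (training && dropout > 0 && !lastLayer) {
        m <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                    nrow(a), ncol(a))
        a <- a * m
        mask[[l]] <- m
      }
    }
    A[[l + 1]] <- a
  }
  list(out = a, cache = list(A = A, Z = Z, mask = mask))
}

# Backward pass from dOut = dL/d(output). For sigmoid output pass
# dZlast = dL/dz directly via `dZLast` (numerically stabler).
mlpBackward <- function(net, cache, dOut = NULL, dZLast = NULL) {
  act <- .activation(net$activation)
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  if (!is.null(dZLast)) {
    delta <- dZLast
  } else {
    z <- cache$Z[[L]]; y <- cache$A[[L + 1]]
    delta <- switch(net$outActivation,
      sigmoid = dOut * y * (1 - y),
      linear = dOut,
      hidden = {
        d <- dOut * act$df(z)
        if (!is.null(cache$mask[[L]])) d <- d * cache$mask[[L]]
        d
      })
  }
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      dA <- delta %*% t(net$W[[l]])
      if (!is.null(cache$mask[[l - 1]])) dA <- dA * cache$mask[[l - 1]]
      delta <- dA * act$df(cache$Z[[l - 1]])
    } else {
      dX <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# --- optimisers over flat lists of parameter arrays ---------------------

optimInit <- function(params, name, lr) {
  zeros <- lapply(params, function(p) array(0, dim = dim(as.matrix(p))))
  list(name = tolower(name), lr = lr, t = 0,
       m = zeros, v = zeros)
}

optimStep <- function(state, params, grads) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    g <- as.matrix(grads[[i]]); p <- as.matrix(params[[i]])
    if (state$name == "sgd") {
      p <- p - state$lr * g
    } else if (state$name == "adam") {
      state$m[[i]] <- 0.9 * state$m[[i]] + 0.1 * g
      state$v[[i]] <- 0.999 * state$v[[i]] + 0.001 * g^2
      mhat <- state$m[[i]] / (1 - 0.9^state$t)
      vhat <- state$v[[i]] / (1 - 0.999^state$t)
      p <- p - state$lr * mhat / (sqrt(vhat) + 1e-8)
    } else if (state$name == "adadelta") {
      rho <- 0.95; eps <- 1e-6
      state$v[[i]] <- rho * state$v[[i]] + (1 - rho) * g^2
      upd <- sqrt(state$m[[i]] + eps) / sqrt(state$v[[i]] + eps) * g
      state$m[[i]] <- rho * state$m[[i]] + (1 - rho) * upd^2
      p <- p - state$lr * upd
    } else stop("unknown optimizer: ", state$name)
    dim(p) <- dim(as.matrix(params[[i]]))
    params[[i]] <- if (is.null(dim(grads[[i]]))) as.numeric(p) else p
  }
  list(state = state, params = params)
}

.netParams <- function(net) c(net$W, net$b)
.netSetParams <- function(net, params) {
  L <- length(net$W)
  net$W <- params[seq_len(L)]
  net$b <- lapply(params[L + seq_len(L)], as.numeric)
  net
}

.bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a feed-forward classifier
#'
#' Mini-batch training of a sigmoid-output MLP under binary cross-entropy.
#' When validation data are supplied, per-epoch validation loss and
#' accuracy (at threshold 0.5) are recorded and the returned weights are
#' the checkpoint from the epoch with the highest validation accuracy
#' (earliest epoch on ties).
#'
#' @param x Numeric feature matrix (rows = studies).
#' @param y 0/1 labels.
#' @param config An [ffnnConfig()].
#' @param epochs Training epochs (canonical protocol: 200).
#' @param batchSize Mini-batch size (canonical protocol: 256).
#' @param xVal,yVal Optional validation data.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @param net Optional pre-initialised network (e.g. from a fusion
#'   builder); when supplied, initialisation is skipped.
#' @return An object of class `ffnn_fit` with elements `net` (checkpoint
#'   weights), `finalNet`, `history` (per-epoch losses/accuracy),
#'   `bestEpoch`, `config`.
#' @export
trainFFNN <- function(x, y, config = ffnnConfig(), epochs = 200L,
                      batchSize = 256L, xVal = NULL, yVal = NULL,
                      seed = 1L, net = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  if (is.null(net)) {
    dims <- c(ncol(x), rep(config$nNeurons, config$nHidden), 1L)
    net <- mlpInit(dims, config$activation, config$init, "sigmoid")
  }
  opt <- optimInit(.netParams(net), config$optimizer, config$learningRate)
  n <- nrow(x)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, net = net)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1, n)]
      fw <- mlpForward(net, x[idx, , drop = FALSE],
                       dropout = config$dropout, training = TRUE)
      p <- as.numeric(fw$out)
      losses <- c(losses, .bceLoss(p, y[idx]))
      dZ <- matrix((p - y[idx]) / length(idx), ncol = 1)
      gr <- mlpBackward(net, fw$cache, dZLast = dZ)
      step <- optimStep(opt, .netParams(net), c(gr$dW, gr$db))
      opt <- step$state
      net <- .netSetParams(net, step$params)
    }
    valLoss <- NA_real_; valAcc <- NA_real_
    if (!is.null(xVal)) {
      pv <- as.numeric(mlpForward(net, as.matrix(xVal))$out)
      valLoss <- .bceLoss(pv, yVal)
      valAcc <- mean((pv >= 0.5) == (yVal == 1))
      if (valAcc > best$acc) {
        best <- list(acc = valAcc, epoch = ep, net = net)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = valLoss, val_acc = valAcc))
  }
  if (is.null(xVal)) best <- list(acc = NA_real_, epoch = epochs, net = net)
  structure(list(net = best$net, finalNet = net, history = hist,
                 bestEpoch = best$epoch, config = config),
            class = "ffnn_fit")
}

#' @describeIn trainFFNN Predict probabilities from a fitted network
#'   (checkpoint weights).
#' @param object A `ffnn_fit`.
#' @param ... Unused.
#' @export
predict.ffnn_fit <- function(object, x, ...) {
  p <- as.numeric(mlpForward(object$net, as.matrix(x))$out)
  if (!is.null(rownames(x))) names(p) <- rownames(x)
  p
}
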