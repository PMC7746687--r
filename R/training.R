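# Grid-search training protocol, applied uniformly to every feed-forward
# model. Two independent rules: per configuration, the checkpoint is the
# epoch with the highest validation accuracy; across the grid, the
# selected configuration is the one whose checkpoint has the lowest
# validation loss. Selection never sees test-split data.

#' Specify a hyperparameter grid
#'
#' @param axes Named list mapping hyperparameter names (arguments of
#'   [ffnnConfig()]) to candidate value vectors. The canonical search
#'   ranges are activation \{ELU, LeakyReLU, Tanh\}, 0-10 hidden layers,
#'   10-500 neurons, optimizer \{Adam, SGD, AdaDelta\}, learning rate
#'   1e-4 to 1e-1, init \{Normal, Xavier, Kaiming\}, dropout 0.3-0.8; the
#'   default desk-scale grid is a small documented subset of them.
#' @param batchSize Mini-batch size (canonical protocol: 256).
#' @param epochs Epochs per configuration (canonical protocol: 200).
#' @param seed Seed; together with the enumeration order it makes the
#'   whole search deterministic.
#' @return A list of class `gridSpec`.
#' @export
gridSpec <- function(axes = list(activation = c("ELU", "Tanh"),
                                 nHidden = c(1L, 2L),
                                 learningRate = c(0.01, 0.001)),
                     batchSize = 256L, epochs = 200L, seed = 1L) {
  stopifnot(length(axes) >= 1, !is.null(names(axes)))
  structure(list(axes = axes, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "gridSpec")
}

#' Run a grid search over feed-forward configurations
#'
#' Enumerates every combination of the grid axes, trains each
#' configuration with [trainFFNN()] (checkpointing the epoch with the
#' highest validation accuracy), and selects the configuration whose
#' checkpoint achieves the lowest validation loss. Ties are broken
#' deterministically by grid enumeration order and logged. Deterministic
#' given the grid seed.
#'
#' @param grid A [gridSpec()].
#' @param x,y Training features and 0/1 labels.
#' @param xVal,yVal Validation features and labels (patient-disjoint from
#'   training).
#' @return List with `records` (one per configuration: config, history,
#'   bestEpoch, valLoss, valAcc, fit), `selected` (the winning record),
#'   `selectedIndex`, and `leaderboard` (a data.frame).
#' @export
runGridSearch <- function(grid, x, y, xVal, yVal) {
  stopifnot(inherits(grid, "gridSpec"))
  if (any(lengths(grid$axes) == 0)) stop("empty grid axis")
  if (length(unique(yVal)) < 2)
    warning("validation set contains a single class; ",
            "selection by validation loss is weakly informative")
  combos <- expand.grid(grid$axes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  records <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfgArgs <- as.list(combos[i, , drop = FALSE])
    cfg <- do.call(ffnnConfig, cfgArgs)
    fit <- trainFFNN(x, y, config = cfg, epochs = grid$epochs,
                     batchSize = grid$batchSize, xVal = xVal, yVal = yVal,
                     seed = grid$seed + i)
    h <- fit$history
    records[[i]] <- list(config = cfg, history = h,
                         bestEpoch = fit$bestEpoch,
                         valLoss = h$val_loss[fit$bestEpoch],
                         valAcc = h$val_acc[fit$bestEpoch],
                         fit = fit)
  }
  valLosses <- vapply(records, `[[`, numeric(1), "valLoss")
  selectedIndex <- which.min(valLosses)   # first minimum: enumeration order
  if (sum(valLosses == valLosses[selectedIndex]) > 1)
    message("validation-loss tie; keeping the earliest configuration ",
            "in grid enumeration order (#", selectedIndex, ")")
  leaderboard <- cbind(combos,
                       data.frame(best_epoch = vapply(records, `[[`,
                                                      integer(1), "bestEpoch"),
                                  val_loss = valLosses,
                                  val_acc = vapply(records, `[[`,
                                                   numeric(1), "valAcc")))
  leaderboard <- leaderboard[order(leaderboard$val_loss), ]
  list(records = records, selected = records[[selectedIndex]],
       selectedIndex = selectedIndex, leaderboard = leaderboard)
}

#' Convergence report over grid-search records
#'
#' Flags configurations whose minimum validation loss falls on the final
#' epoch, i.e. models that were still improving when training stopped
#' (trained models are expected to reach their loss minimum before the
#' last iteration). Ties take the earliest epoch by convention.
#'
#' @param records Record list from [runGridSearch()] (or any list with a
#'   `history` data.frame holding `val_loss`).
#' @return data.frame with columns config index, `minLossEpoch`,
#'   `nEpochs`, `converged`.
#' @export
earlyConvergenceReport <- function(records) {
  rows <- lapply(seq_along(records), function(i) {
    h <- records[[i]]$history
    minEp <- which.min(h$val_loss)
    data.frame(config = i, minLossEpoch = minEp, nEpochs = nrow(h),
               converged = minEp < nrow(h))
  })
  out <- do.call(rbind, rows)
  if (any(!out$converged))
    warning(sum(!out$converged),
            " configuration(s) reached their minimum validation loss at ",
            "the final epoch; consider more epochs")
  out
}
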