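# CT preprocessing and sliding-window dataset construction.
# Intensities are clipped to [-1000, 900] HU, each axial slice resized to
# a square target (224 x 224 by default), and values zero-centered by
# subtracting a fixed constant (the clip-range midpoint, -50). Windows of
# 24 consecutive slices are labeled positive when strictly more than 35%
# of their slices are positive.

.HU_CLIP <- c(-1000, 900)
.WINDOW_LENGTH <- 24L
.WINDOW_POS_FRACTION <- 0.35

#' A preprocessed CT volume
#'
#' @slot studyId Study identifier.
#' @slot voxels Numeric array (target x target x slices), clipped and
#'   zero-centered.
#' @slot sliceLabels Integer 0/1 per axial slice.
#' @slot targetSize Spatial side length in voxels.
#' @export
setClass("PreprocessedVolume",
  representation(studyId = "character", voxels = "array",
                 sliceLabels = "integer", targetSize = "integer"))

setValidity("PreprocessedVolume", function(object) {
  d <- dim(object@voxels)
  msg <- character()
  if (length(d) != 3)
    msg <- c(msg, "voxels must be a 3-D array")
  else {
    if (d[1] != object@targetSize || d[2] != object@targetSize)
      msg <- c(msg, "spatial dimensions must equal targetSize x targetSize")
    if (d[3] != length(object@sliceLabels))
      msg <- c(msg, "sliceLabels length must equal the slice count")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PreprocessedVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("PreprocessedVolume %s: %dx%dx%d (%d positive slices)\n",
              object@studyId, d[1], d[2], d[3], sum(object@sliceLabels)))
})

#' A batch of sliding windows over one study
#'
#' Holds the preprocessed voxels together with the window start indices
#' and window-level labels; individual 24-slice sub-volumes are extracted
#' lazily by start index.
#'
#' @slot studyId Study identifier.
#' @slot voxels Preprocessed voxel array (padded to at least 24 slices).
#' @slot starts Window start slice indices.
#' @slot windowLength Slices per window (24).
#' @slot windowLabels Integer 0/1 per window.
#' @slot stride Stride used to place the windows.
#' @export
setClass("WindowBatch",
  representation(studyId = "character", voxels = "array",
                 starts = "integer", windowLength = "integer",
                 windowLabels = "integer", stride = "integer"))

setValidity("WindowBatch", function(object) {
  n <- dim(object@voxels)[3]
  if (any(object@starts < 1L |
          object@starts + object@windowLength - 1L > n))
    return("window starts must keep all windows inside the volume")
  if (length(object@windowLabels) != length(object@starts))
    return("one label per window required")
  TRUE
})

setMethod("show", "WindowBatch", function(object) {
  cat(sprintf("WindowBatch %s: %d windows of %d slices (stride %d, %d positive)\n",
              object@studyId, length(object@starts), object@windowLength,
              object@stride, sum(object@windowLabels)))
})

#' Clip intensities to the CT Hounsfield working range
#'
#' Clips to [-1000, 900] HU. Idempotent: `clipHU(clipHU(x)) == clipHU(x)`.
#'
#' @param x Numeric array of Hounsfield-like intensities.
#' @return Clipped array.
#' @export
clipHU <- function(x) pmin(pmax(x, .HU_CLIP[1]), .HU_CLIP[2])

#' Preprocess a raw CT volume
#'
#' Clips intensities to [-1000, 900] HU, resizes every axial slice to
#' `targetSize` x `targetSize` (bilinear), and zero-centers by subtracting
#' a fixed constant (default: the clip-range midpoint, -50).
#'
#' @param volume 3-D numeric array (height x width x slices) with at
#'   least one slice and finite voxels.
#' @param sliceLabels Optional integer 0/1 per slice (default all 0).
#' @param studyId Identifier stored with the result.
#' @param targetSize Output spatial side length (default 224).
#' @param center Zero-centering constant subtracted after clipping.
#' @return A [PreprocessedVolume-class].
#' @export
preprocessVolume <- function(volume, sliceLabels = NULL, studyId = "study",
                             targetSize = 224L, center = -50) {
  volume <- as.array(volume)
  storage.mode(volume) <- "double"
  d <- dim(volume)
  if (length(d) != 3 || d[3] < 1)
    stop("volume must be a 3-D array with at least one slice")
  if (any(!is.finite(volume)))
    stop("volume contains non-finite voxels")
  if (is.null(sliceLabels)) sliceLabels <- integer(d[3])
  stopifnot(length(sliceLabels) == d[3])
  volume <- clipHU(volume)
  targetSize <- as.integer(targetSize)
  if (d[1] != targetSize || d[2] != targetSize) {
    out <- array(0, c(targetSize, targetSize, d[3]))
    for (s in seq_len(d[3]))
      out[, , s] <- EBImage::resize(volume[, , s], w = targetSize,
                                    h = targetSize)
    volume <- out
  }
  volume <- volume - center
  new("PreprocessedVolume", studyId = studyId, voxels = volume,
      sliceLabels = as.integer(sliceLabels), targetSize = targetSize)
}

# reflect-pad a short volume (and its labels) to the window length
.reflectPad <- function(voxels, sliceLabels, target) {
  n <- dim(voxels)[3]
  idx <- seq_len(n)
  ext <- if (n == 1) 1L else rev(seq_len(n))[-1]   # reflected tail
  while (length(idx) < target) idx <- c(idx, ext)
  idx <- idx[seq_len(target)]
  list(voxels = voxels[, , idx, drop = FALSE],
       sliceLabels = sliceLabels[idx])
}

#' Build sliding windows over a preprocessed volume
#'
#' Places 24-slice windows at the given stride so that all slices are
#' covered (a final window is anchored at the last admissible start when
#' the stride leaves a remainder). A window is labeled positive when
#' strictly more than 35% of its slices are positive: 9 of 24 positive
#' slices (37.5%) is positive, 8 of 24 (33.3%) is negative. Volumes
#' shorter than 24 slices are reflect-padded with a warning.
#'
#' @param volume A [PreprocessedVolume-class].
#' @param stride Slice stride between windows (default 12, i.e. 50%
#'   overlap for training; use 24 for non-overlapping inference windows).
#' @return A [WindowBatch-class].
#' @export
makeWindows <- function(volume, stride = 12L) {
  stopifnot(is(volume, "PreprocessedVolume"), stride >= 1L)
  voxels <- volume@voxels
  labels <- volume@sliceLabels
  n <- dim(voxels)[3]
  if (n < .WINDOW_LENGTH) {
    warning("volume ", volume@studyId, " has ", n,
            " slices; reflect-padding to ", .WINDOW_LENGTH)
    padded <- .reflectPad(voxels, labels, .WINDOW_LENGTH)
    voxels <- padded$voxels
    labels <- padded$sliceLabels
    n <- .WINDOW_LENGTH
  }
  lastStart <- n - .WINDOW_LENGTH + 1L
  starts <- seq.int(1L, lastStart, by = as.integer(stride))
  if (starts[length(starts)] != lastStart) starts <- c(starts, lastStart)
  winLabels <- vapply(starts, function(s) {
    frac <- mean(labels[s:(s + .WINDOW_LENGTH - 1L)])
    as.integer(frac > .WINDOW_POS_FRACTION)
  }, integer(1))
  new("WindowBatch", studyId = volume@studyId, voxels = voxels,
      starts = as.integer(starts), windowLength = .WINDOW_LENGTH,
      windowLabels = winLabels, stride = as.integer(stride))
}

# extract one window as [slices, h, w] array
.windowArray <- function(batch, i) {
  s <- batch@starts[i]
  aperm(batch@voxels[, , s:(s + batch@windowLength - 1L), drop = FALSE],
        c(3, 1, 2))
}

#' Focal loss for binary classification
#'
#' \eqn{FL(p, y) = -\alpha_y (1 - p_y)^\gamma \log p_y} with
#' \eqn{p_y = p} for positives and \eqn{1 - p} for negatives, and
#' \eqn{\alpha_y = \alpha} for positives, \eqn{1 - \alpha} for negatives.
#' With `gamma = 0` and `alpha = 0.5` it reduces to 0.5 times the binary
#' cross-entropy; `gamma > 0` down-weights well-classified examples to
#' alleviate class imbalance between sliding windows.
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y 0/1 labels.
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Class-balance weight in [0, 1].
#' @return Per-sample loss values (non-negative).
#' @export
focalLoss <- function(p, y, gamma = 2, alpha = 0.5) {
  stopifnot(gamma >= 0, alpha >= 0, alpha <= 1)
  n <- max(length(p), length(y))
  p <- rep_len(pmin(pmax(p, 1e-12), 1 - 1e-12), n)
  y <- rep_len(y, n)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

# d(mean focal loss)/d(logit z), vectorised; used by the CNN trainer
.focalGradLogit <- function(p, y, gamma, alpha) {
  n <- max(length(p), length(y))
  p <- rep_len(pmin(pmax(p, 1e-12), 1 - 1e-12), n)
  y <- rep_len(y, n)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  # dL/dpt = at * (gamma * (1-pt)^(gamma-1) * log(pt) - (1-pt)^gamma / pt)
  dLdpt <- at * (gamma * (1 - pt)^(gamma - 1) * log(pt) -
                   (1 - pt)^gamma / pt)
  # dpt/dz = pt * (1 - pt) * sign, with sign +1 for y=1 and -1 for y=0
  sgn <- ifelse(y == 1, 1, -1)
  dLdpt * sgn * p * (1 - p) / length(p)
}
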