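# Statistical evaluation protocol: AUROC (Mann-Whitney form with tie
# correction), Youden operating-point selection on validation data,
# confusion metrics with Wilson score intervals, DeLong and bootstrap
# AUROC confidence intervals, paired bootstrap model comparison, and the
# subsegmental-excluded subgroup analysis.

.alignPreds <- function(predictions, labels) {
  if (is(predictions, "PredictionSet")) predictions <- probabilities(predictions)
  if (!is.null(names(predictions)) && !is.null(names(labels)))
    labels <- labels[names(predictions)]
  list(p = as.numeric(predictions), y = as.numeric(labels))
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic normalised by the number of positive-negative
#' pairs; tied scores contribute 1/2. Computed via midranks.
#'
#' @param predictions Numeric scores (or a [PredictionSet-class]); when
#'   both are named, labels are aligned by name.
#' @param labels 0/1 labels. Both classes must be present.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(predictions, labels) {
  al <- .alignPreds(predictions, labels)
  pos <- al$y == 1
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("auroc requires both classes to be present")
  r <- rank(al$p)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Select the Youden operating point on validation data
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over candidate
#' thresholds (midpoints between adjacent sorted unique scores, plus 0
#' and 1), classifying positive at probability >= threshold. Ties in J
#' are broken towards the lower threshold (higher sensitivity).
#'
#' @param predictions Validation scores (or a [PredictionSet-class]).
#' @param labels Validation 0/1 labels; both classes must be present.
#' @return List with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
selectOperatingPoint <- function(predictions, labels) {
  al <- .alignPreds(predictions, labels)
  p <- al$p; y <- al$y
  if (length(unique(y)) < 2)
    stop("operating-point selection requires both classes")
  u <- sort(unique(p))
  cand <- sort(unique(c(0, (utils::head(u, -1) + utils::tail(u, -1)) / 2, 1)))
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  J <- vapply(cand, function(th) {
    sens <- sum(p >= th & y == 1) / nPos
    spec <- sum(p < th & y == 0) / nNeg
    sens + spec - 1
  }, numeric(1))
  best <- which(J == max(J))[1]   # candidates ascending: lowest threshold
  sens <- sum(p >= cand[best] & y == 1) / nPos
  spec <- sum(p < cand[best] & y == 0) / nNeg
  list(threshold = cand[best], J = max(J), sensitivity = sens,
       specificity = spec)
}

#' Confusion-matrix metrics at a threshold
#'
#' Sensitivity, specificity, accuracy, PPV and NPV from the standard 2x2
#' table, classifying positive at probability >= threshold. Ratios with a
#' zero denominator are returned as `NaN` with a warning.
#'
#' @param predictions Scores (or a [PredictionSet-class]).
#' @param labels 0/1 labels.
#' @param threshold Operating threshold in [0, 1].
#' @return Named list with the five metrics and the 2x2 counts
#'   (`tp`, `fp`, `tn`, `fn`).
#' @export
confusionMetrics <- function(predictions, labels, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  al <- .alignPreds(predictions, labels)
  pred <- al$p >= threshold
  y <- al$y == 1
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  list(sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       accuracy = (tp + tn) / length(y),
       ppv = ratio(tp, tp + fp, "PPV"),
       npv = ratio(tn, tn + fn, "NPV"),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# DeLong structural components: for each positive the fraction of
# negatives scored below it (ties 1/2), and vice versa.
.delongComponents <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  m <- length(pos); n <- length(neg)
  rAll <- rank(c(pos, neg))
  v10 <- (rAll[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (rAll[m + seq_len(n)] - rank(neg)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for the AUROC
#'
#' Nonparametric structural-component variance estimate with a normal
#' approximation, truncated to [0, 1]. When the variance degenerates to
#' zero (perfect or perfectly reversed separation) the interval falls
#' back to a bootstrap percentile interval with a notice.
#'
#' @param predictions Scores (or a [PredictionSet-class]).
#' @param labels 0/1 labels, at least two per class.
#' @param level Confidence level (default 0.95).
#' @param nBoot Bootstrap replicates for the degenerate fallback.
#' @return List with `auc`, `lower`, `upper`, `se`, `method`.
#' @export
delongCI <- function(predictions, labels, level = 0.95, nBoot = 1000L) {
  al <- .alignPreds(predictions, labels)
  p <- al$p; y <- al$y
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("DeLong CI requires at least two studies per class")
  dc <- .delongComponents(p, y)
  v <- stats::var(dc$v10) / length(dc$v10) +
    stats::var(dc$v01) / length(dc$v01)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (v <= 0) {
    message("degenerate DeLong variance (AUROC ", round(dc$auc, 3),
            "); reporting a bootstrap percentile interval instead")
    ab <- .bootstrapAUROC(p, y, nBoot = nBoot, seed = 0L)
    qs <- stats::quantile(ab, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    return(list(auc = dc$auc, lower = max(0, qs[1]), upper = min(1, qs[2]),
                se = 0, method = "bootstrap"))
  }
  se <- sqrt(v)
  list(auc = dc$auc, lower = max(0, dc$auc - z * se),
       upper = min(1, dc$auc + z * se), se = se, method = "delong")
}

# percentile bootstrap of the AUROC (study-level resampling); replicates
# with a single class are redrawn
.bootstrapAUROC <- function(p, y, nBoot = 1000L, seed = 0L) {
  set.seed(seed)
  n <- length(p)
  out <- numeric(nBoot)
  for (i in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    out[i] <- auroc(p[idx], y[idx])
  }
  out
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval; the lower bound is exactly 0 for 0
#' successes and the upper bound exactly 1 for `trials` successes.
#'
#' @param successes Number of successes (0 <= successes <= trials).
#' @param trials Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
wilsonCI <- function(successes, trials, level = 0.95) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (phat + z^2 / (2 * trials)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / trials +
                               z^2 / (4 * trials^2))
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Paired bootstrap comparison of two models' AUROCs
#'
#' Paired study-level resampling of the two prediction sets; the
#' two-sided p-value is `2 * min(P(diff <= 0), P(diff >= 0))` over the
#' bootstrap distribution of the AUROC difference, with the +1
#' small-sample correction. Replicates containing a single class are
#' redrawn. Deterministic given `seed`.
#'
#' @param predsA,predsB Scores (or [PredictionSet-class]) covering
#'   identical study ids.
#' @param labels 0/1 labels (named, when the predictions are named).
#' @param nBoot Bootstrap replicates (canonical protocol: 1000).
#' @param seed Seed.
#' @return List with `aurocA`, `aurocB`, `difference`, `pValue`,
#'   `nBoot`, and the replicate differences `diffs`.
#' @export
bootstrapCompare <- function(predsA, predsB, labels, nBoot = 1000L,
                             seed = 1L) {
  if (is(predsA, "PredictionSet") && is(predsB, "PredictionSet") &&
      !setequal(predsA@studyIds, predsB@studyIds))
    stop("prediction sets must cover identical study ids")
  a <- .alignPreds(predsA, labels)
  b <- .alignPreds(predsB, labels)
  if (length(a$p) != length(b$p))
    stop("prediction sets must cover identical study ids")
  y <- a$y
  set.seed(seed)
  n <- length(y)
  diffs <- numeric(nBoot)
  nRedrawn <- 0L
  for (i in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      nRedrawn <- nRedrawn + 1L
    }
    diffs[i] <- auroc(a$p[idx], y[idx]) - auroc(b$p[idx], y[idx])
  }
  if (nRedrawn > 0)
    message(nRedrawn, " single-class bootstrap replicate(s) redrawn")
  pLe <- (sum(diffs <= 0) + 1) / (nBoot + 1)
  pGe <- (sum(diffs >= 0) + 1) / (nBoot + 1)
  list(aurocA = auroc(a$p, y), aurocB = auroc(b$p, y),
       difference = auroc(a$p, y) - auroc(b$p, y),
       pValue = min(1, 2 * min(pLe, pGe)), nBoot = nBoot, diffs = diffs)
}

.metricRow <- function(name, successes, trials, level = 0.95) {
  est <- if (trials == 0) NaN else successes / trials
  ci <- if (trials == 0) c(NA_real_, NA_real_)
        else wilsonCI(successes, trials, level)
  data.frame(metric = name, estimate = est, lower = ci[1], upper = ci[2],
             successes = successes, trials = trials,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate a model at a fixed operating point
#'
#' Builds an [EvalReport-class]: AUROC with DeLong and bootstrap 95%
#' intervals, and the five confusion metrics with Wilson intervals at the
#' given threshold (typically the Youden point selected on validation
#' with [selectOperatingPoint()]).
#'
#' @param predictions Test scores (or a [PredictionSet-class]).
#' @param labels Test 0/1 labels.
#' @param threshold Operating threshold.
#' @param modelName,split,subgroup Identifiers for the report.
#' @param nBoot Bootstrap replicates for the AUROC interval.
#' @param seed Seed for the bootstrap.
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(predictions, labels, threshold,
                          modelName = "model", split = "test",
                          subgroup = "all", nBoot = 1000L, seed = 1L) {
  al <- .alignPreds(predictions, labels)
  dl <- delongCI(al$p, al$y, nBoot = nBoot)
  ab <- .bootstrapAUROC(al$p, al$y, nBoot = nBoot, seed = seed)
  bootCI <- stats::quantile(ab, c(0.025, 0.975), names = FALSE)
  cm <- withCallingHandlers(
    confusionMetrics(al$p, al$y, threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  metrics <- rbind(
    .metricRow("sensitivity", cm$tp, cm$tp + cm$fn),
    .metricRow("specificity", cm$tn, cm$tn + cm$fp),
    .metricRow("accuracy", cm$tp + cm$tn, length(al$y)),
    .metricRow("ppv", cm$tp, cm$tp + cm$fp),
    .metricRow("npv", cm$tn, cm$tn + cm$fn))
  new("EvalReport", modelName = modelName, split = split,
      subgroup = subgroup, threshold = threshold,
      auroc = dl$auc,
      aurocDeLongCI = c(dl$lower, dl$upper),
      aurocBootCI = c(max(0, min(bootCI[1], dl$auc)),
                      min(1, max(bootCI[2], dl$auc))),
      metrics = metrics, n = length(al$y), nBoot = as.integer(nBoot))
}

#' Subgroup evaluation excluding subsegmental-only positives
#'
#' Produces paired reports: one over all studies and one over the subset
#' that drops positives whose PE extent is subsegmental-only (negatives
#' are retained), mirroring the clinical question of performance on
#' unambiguously treatable PE.
#'
#' @param predictions Test scores (or a [PredictionSet-class]).
#' @param labels Named 0/1 labels.
#' @param extent Named PE extent per study ("central", "segmental",
#'   "subsegmental", "none").
#' @param threshold Operating threshold.
#' @param ... Passed to [evaluateModel()].
#' @return List with elements `all` and `excludingSubsegmental`, both
#'   [EvalReport-class].
#' @export
subgroupReport <- function(predictions, labels, extent, threshold, ...) {
  if (is(predictions, "PredictionSet")) predictions <- probabilities(predictions)
  ids <- names(predictions)
  stopifnot(!is.null(ids), all(ids %in% names(labels)),
            all(ids %in% names(extent)))
  keep <- ids[!(labels[ids] == 1 & extent[ids] == "subsegmental")]
  if (length(keep) == 0) stop("empty subgroup after filtering")
  if (length(unique(labels[keep])) < 2)
    stop("subgroup contains a single class; AUROC undefined")
  list(all = evaluateModel(predictions, labels[ids], threshold,
                           subgroup = "all", ...),
       excludingSubsegmental = evaluateModel(predictions[keep],
                                             labels[keep], threshold,
                                             subgroup = "excluding_subsegmental",
                                             ...))
}
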