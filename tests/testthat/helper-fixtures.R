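# Shared fixtures, built in code and memoised per test run.

.fixtures <- new.env(parent = emptyenv())

# a small but complete cohort: all splits populated, both classes present
smallCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generateCohort(
      cohortSpec(nPatients = 40L, volumeShape = c(16L, 16L),
                 slicesPerStudy = c(24L, 30L), seed = 101L))
  }
  .fixtures$cohort
}

# deterministic toy prediction/label pairs for evaluation tests
toyScores <- function(n = 40L, seed = 7L) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  p <- plogis(qlogis(0.5) + 1.5 * (y - 0.5) + rnorm(n))
  list(p = p, y = y)
}

# exhaustive pairwise AUROC oracle (ties count 1/2)
pairwiseAUROC <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force Youden point over midpoint candidates (>= convention)
bruteYouden <- function(p, y) {
  u <- sort(unique(p))
  cand <- sort(unique(c(0, (head(u, -1) + tail(u, -1)) / 2, 1)))
  J <- sapply(cand, function(th)
    mean(p[y == 1] >= th) + mean(p[y == 0] < th) - 1)
  list(threshold = cand[which(J == max(J))[1]], J = max(J))
}
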