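test_that("auroc matches its defining examples", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.3, 0.3), c(1, 0)), 0.5)        # complete tie
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auroc equals the exhaustive pairwise oracle with ties", {
  set.seed(61)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    p <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auroc(p, y), pairwiseAUROC(p, y))
  }
})

test_that("the Youden point matches brute force and breaks ties low", {
  # perfectly separated scores: J = 1, threshold in the gap
  sep <- selectOperatingPoint(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$J, 1)
  expect_gt(sep$threshold, 0.2)
  expect_lt(sep$threshold, 0.8)

  op <- selectOperatingPoint(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  bf <- bruteYouden(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(op$threshold, bf$threshold)
  expect_equal(op$J, bf$J)

  set.seed(67)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    p <- round(runif(n), 2)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    op <- selectOperatingPoint(p, y)
    bf <- bruteYouden(p, y)
    expect_equal(op$J, bf$J)
    expect_equal(op$threshold, bf$threshold)  # lowest threshold on ties
  }
  expect_error(selectOperatingPoint(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("confusion metrics reproduce hand-computed tables", {
  perfect <- confusionMetrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 ppv = 1, npv = 1))
  # TP=9 FN=1 TN=8 FP=2
  p <- c(rep(0.9, 9), 0.1, rep(0.1, 8), rep(0.9, 2))
  y <- c(rep(1, 10), rep(0, 10))
  cm <- confusionMetrics(p, y, 0.5)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$ppv, 9 / 11)
  expect_equal(cm$npv, 8 / 9)
  expect_equal(cm$accuracy, 17 / 20)
  # no predicted positives: PPV undefined
  expect_warning(cm0 <- confusionMetrics(c(0.1, 0.2), c(1, 0), 0.9), "PPV")
  expect_true(is.nan(cm0$ppv))
  # >= threshold convention: a score exactly at the threshold is positive
  suppressWarnings(
    expect_equal(confusionMetrics(c(0.5), c(1), 0.5)$sensitivity, 1))
})

test_that("the Wilson interval solves the score inequality", {
  # independent oracle: the interval endpoints are the roots of
  # (phat - p)^2 = z^2 p (1 - p) / n
  wilsonRoot <- function(x, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2)
    phat <- x / n
    f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
    lower <- if (x == 0) 0 else
      uniroot(f, c(1e-12, phat - 1e-12), tol = 1e-14)$root
    upper <- if (x == n) 1 else
      uniroot(f, c(phat + 1e-12, 1 - 1e-12), tol = 1e-14)$root
    c(lower, upper)
  }
  for (case in list(c(0, 10), c(10, 10), c(5, 10), c(1, 7), c(19, 20),
                    c(50, 100))) {
    got <- wilsonCI(case[1], case[2])
    want <- wilsonRoot(case[1], case[2])
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
  expect_equal(unname(wilsonCI(0, 10)[1]), 0)   # exact boundary
  expect_equal(unname(wilsonCI(10, 10)[2]), 1)
  expect_error(wilsonCI(5, 0), "trials")
})

test_that("DeLong intervals agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (i in 1:5) {
    y <- c(rep(1, 30), rep(0, 40))
    p <- plogis(y + rnorm(70))
    got <- delongCI(p, y)
    ref <- suppressMessages(pROC::ci.auc(y, p, method = "delong"))
    expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-12)
    expect_equal(got$lower, max(0, as.numeric(ref[1])), tolerance = 1e-9)
    expect_equal(got$upper, min(1, as.numeric(ref[3])), tolerance = 1e-9)
  }
})

test_that("DeLong variance scales as expected under duplication and flips", {
  set.seed(73)
  y <- c(rep(1, 20), rep(0, 25))
  p <- plogis(0.8 * y + rnorm(45))
  one <- delongCI(p, y)
  two <- delongCI(rep(p, 2), rep(y, 2))
  # duplicating every study roughly halves the variance
  expect_equal(two$se^2, one$se^2 / 2, tolerance = 0.05)
  flip <- delongCI(1 - p, 1 - y)
  expect_equal(flip$upper - flip$lower, one$upper - one$lower,
               tolerance = 1e-12)
  expect_error(delongCI(c(0.2, 0.8), c(0, 1)), "two studies per class")
})

test_that("degenerate DeLong variance falls back to the bootstrap", {
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(0.9, 10), rep(0.1, 10))
  expect_message(ci <- delongCI(p, y), "degenerate")
  expect_equal(ci$method, "bootstrap")
  expect_true(ci$lower <= 1 && ci$upper == 1)
})

test_that("paired bootstrap comparison honours its contracts", {
  d <- toyScores(60)
  same <- bootstrapCompare(d$p, d$p, d$y, nBoot = 200, seed = 1)
  expect_equal(same$pValue, 1)
  expect_true(all(same$diffs == 0))

  r1 <- bootstrapCompare(d$p, rev(d$p), d$y, nBoot = 200, seed = 5)
  r2 <- bootstrapCompare(d$p, rev(d$p), d$y, nBoot = 200, seed = 5)
  expect_identical(r1$diffs, r2$diffs)
  expect_identical(r1$pValue, r2$pValue)

  y <- c(rep(1, 25), rep(0, 25))
  a <- y * 0.8 + 0.1           # perfect
  b <- (1 - y) * 0.8 + 0.1     # anti-perfect
  ext <- bootstrapCompare(a, b, y, nBoot = 1000, seed = 2)
  expect_lt(ext$pValue, 0.01)
  expect_equal(ext$difference, 1)

  expect_error(bootstrapCompare(mkPred <- a[1:10], b, y), "identical study ids")
})

test_that("evaluation reports bracket their point estimates", {
  d <- toyScores(80)
  rep_ <- evaluateModel(setNames(d$p, paste0("S", 1:80)),
                        setNames(d$y, paste0("S", 1:80)),
                        threshold = 0.5, nBoot = 200, seed = 1)
  expect_s4_class(rep_, "EvalReport")
  expect_true(rep_@aurocDeLongCI[1] <= rep_@auroc)
  expect_true(rep_@aurocDeLongCI[2] >= rep_@auroc)
  m <- rep_@metrics
  expect_true(all(m$lower <= m$estimate + 1e-12))
  expect_true(all(m$upper >= m$estimate - 1e-12))
  expect_setequal(m$metric, c("sensitivity", "specificity", "accuracy",
                              "ppv", "npv"))
})

test_that("the subsegmental subgroup drops only subsegmental positives", {
  set.seed(79)
  ids <- paste0("S", 1:20)
  y <- setNames(c(rep(1, 10), rep(0, 10)), ids)
  ext <- setNames(c(rep("subsegmental", 3), rep("segmental", 7),
                    rep("none", 10)), ids)
  p <- setNames(plogis(2 * (y - 0.5) + rnorm(20, sd = 0.8)), ids)
  rep2 <- subgroupReport(p, y, ext, threshold = 0.5, nBoot = 100, seed = 1)
  expect_equal(rep2$all@n, 20L)
  expect_equal(rep2$excludingSubsegmental@n, 17L)  # negatives retained

  # no subsegmental positives: both reports identical
  ext2 <- setNames(c(rep("segmental", 10), rep("none", 10)), ids)
  rep3 <- subgroupReport(p, y, ext2, threshold = 0.5, nBoot = 100, seed = 1)
  expect_equal(rep3$all@auroc, rep3$excludingSubsegmental@auroc)
  expect_equal(rep3$all@metrics$estimate,
               rep3$excludingSubsegmental@metrics$estimate)

  # all positives subsegmental: single-class subgroup is an error
  ext3 <- setNames(c(rep("subsegmental", 10), rep("none", 10)), ids)
  expect_error(subgroupReport(p, y, ext3, threshold = 0.5), "single class")
})
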