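test_that("Cohen's d reproduces the study's printed effect sizes", {
  # pooled-SD d from the rounded printed group summaries
  expect_lt(abs(cohensD(82.31, 6.41, 34, 58.44, 8.78, 12) - 3.373) / 3.373,
            0.005)
  expect_lt(abs(cohensD(67.29, 9.52, 34, 72.08, 6.08, 12) - 0.545) / 0.545,
            0.005)
  expect_equal(cohensD(5, 1, 10, 5, 2, 10), 0)
  expect_error(cohensD(1, 0, 10, 2, 1, 10), "positive")
  expect_error(cohensD(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("two-group comparison routes by Shapiro-Wilk normality", {
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30)
  r <- compareContinuous(x, y)
  expect_equal(r$test, "t")
  expect_equal(r$p, t.test(x, y, var.equal = TRUE)$p.value)

  xs <- exp(rnorm(40, sd = 1.5)); ys <- exp(rnorm(40, sd = 1.5))
  rs <- compareContinuous(xs, ys)
  expect_equal(rs$test, "mann-whitney")

  # extreme separation
  expect_lt(compareContinuous(rnorm(20), rnorm(20) + 10)$p, 1e-6)
  expect_error(compareContinuous(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("the routed test keeps its nominal size at the study's n", {
  set.seed(42)
  p <- replicate(300, compareContinuous(rnorm(34), rnorm(12))$p)
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.11)
})

test_that("categorical comparison routes between Fisher and chi-square", {
  r <- compareCategorical(matrix(c(20, 20, 20, 20), 2))
  expect_equal(r$test, "chi-square")
  expect_equal(r$p, 1.0)

  # diagonal table: two-sided Fisher p = 2 / choose(20, 10), verified by
  # hypergeometric enumeration
  rf <- compareCategorical(matrix(c(10, 0, 0, 10), 2))
  expect_equal(rf$test, "fisher")
  pEnum <- sum(dhyper(0:10, 10, 10, 10)[dhyper(0:10, 10, 10, 10) <=
                                          dhyper(10, 10, 10, 10) + 1e-12])
  expect_equal(rf$p, pEnum, tolerance = 1e-12)
  expect_equal(rf$p, 2 / choose(20, 10), tolerance = 1e-12)

  # dyspnea counts (0/34 vs 9/12): smallest expected cell < 5 -> Fisher
  expect_equal(compareCategorical(matrix(c(34, 0, 3, 9), 2))$test, "fisher")
  expect_error(compareCategorical(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  x <- 1:20
  expect_equal(spearmanCorr(x, x)$rho, 1)
  expect_equal(spearmanCorr(x, -x^3)$rho, -1)
  expect_equal(spearmanCorr(x, x)$p, 0)

  # hand-computable set: d^2 = (1,1,1,1,0) -> rho = 1 - 6*4/120 = 0.8
  h <- spearmanCorr(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(h$rho, 0.8)
  tval <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(h$p, 2 * pt(-abs(tval), 3))
  expect_error(spearmanCorr(rep(1, 6), 1:6), "constant")
})

test_that("ROC analysis matches brute-force pair counting and pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (rep in 1:10) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    scores <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- rocAnalysis(scores, labels, "higher_is_positive")
    pos <- scores[labels]; neg <- scores[!labels]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, brute, tolerance = 1e-12)
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$aucCi95, ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("ROC handles separation, direction, and Youden tie-breaks", {
  r <- rocAnalysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$direction, "higher_is_positive")

  # lower-is-positive marker: auto-detected, cutoff in original units,
  # positives classified as score <= cutoff
  rl <- rocAnalysis(c(10, 11, 12, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(rl$direction, "lower_is_positive")
  expect_equal(rl$auc, 1)
  expect_equal(rl$cutoff, 3)

  # uninformative scores at moderate n stay near 0.5
  set.seed(10)
  r0 <- rocAnalysis(rnorm(400), rep(c(0, 1), 200))
  expect_lt(abs(r0$auc - 0.5), 0.12)

  expect_error(rocAnalysis(rnorm(5), rep(1, 5)), "both classes")
})

test_that("DeLong test agrees with pROC and controls its null size", {
  skip_if_not_installed("pROC")
  set.seed(13)
  labels <- rep(c(TRUE, FALSE), c(40, 60))
  a <- rnorm(100) + labels * 1.2
  b <- rnorm(100) + labels * 0.3
  d <- delongTest(a, b, labels)
  pr <- pROC::roc.test(pROC::roc(labels, a, direction = "<", quiet = TRUE),
                       pROC::roc(labels, b, direction = "<", quiet = TRUE),
                       method = "delong")
  expect_equal(d$p, pr$p.value, tolerance = 1e-9)

  # informative vs pure-noise marker at n = 200
  set.seed(14)
  lab2 <- rep(c(TRUE, FALSE), each = 100)
  inf <- rnorm(200) + lab2 * 1.5
  noise <- rnorm(200)
  expect_lt(delongTest(inf, noise, lab2)$p, 0.01)

  # identical markers: degenerate variance raises
  expect_error(delongTest(a, a, labels), "degenerate")

  set.seed(15)
  rej <- mean(replicate(300, {
    l <- rep(c(TRUE, FALSE), c(20, 26))
    delongTest(rnorm(46), rnorm(46), l)$p < 0.05
  }))
  expect_gt(rej, 0.01); expect_lt(rej, 0.11)
})

test_that("odds-ratio identities reproduce the printed regression rows", {
  r <- orFromCoef(1.216, 0.598)
  expect_equal(round(r$or, 3), 3.374)
  expect_equal(round(r$ciLow, 3), 1.045)
  expect_equal(round(r$ciHigh, 3), 10.893)
  expect_equal(round(orFromCoef(-0.01211, 0.0045)$or, 3), 0.988)
  expect_equal(orFromCoef(0, 1)$or, 1)
})

test_that("logistic fits report Wald ORs and detect separation", {
  set.seed(19)
  # OR = exp(coef) exactly, and the 2x2 collapsed fit equals the
  # cross-product ratio
  x <- rep(c(0, 1, 0, 1), c(20, 10, 5, 15))
  y <- rep(c(0, 0, 1, 1), c(20, 10, 5, 15))
  f <- fitLogisticModel(data.frame(x = x), y)
  expect_equal(f$coefficients$or, exp(f$coefficients$coef))
  expect_equal(f$coefficients$or[2], (15 * 20) / (10 * 5), tolerance = 1e-6)

  # null predictor: coefficient ~ 0
  x0 <- rnorm(400); y0 <- rbinom(400, 1, 0.4)
  f0 <- fitLogisticModel(data.frame(x = x0), y0)
  expect_lt(abs(f0$coefficients$coef[2]), 2 * f0$coefficients$se[2] + 0.2)

  # parameter recovery at a study-like slope (-0.012 per mm/s)
  set.seed(20)
  sx <- rnorm(400, 900, 250)
  py <- plogis(10.8 - 0.012 * sx)
  sy <- rbinom(400, 1, py)
  fr <- fitLogisticModel(data.frame(speed = sx), sy)
  expect_lt(abs(fr$coefficients$coef[2] - (-0.012)),
            2 * fr$coefficients$se[2])

  xs <- c(rnorm(20, -3), rnorm(20, 3)); ys <- rep(c(0, 1), each = 20)
  expect_error(fitLogisticModel(data.frame(x = xs), ys), "separation")
})

test_that("bootstrap optimism is near zero for a prespecified score", {
  set.seed(25)
  dat <- data.frame(copd = rep(c(1, 0), c(12, 34)),
                    speedmax = c(rnorm(12, 760, 85), rnorm(34, 1074, 320)))
  bv <- bootstrapOptimism(dat, list(outcome = "copd",
                                    predictors = "speedmax",
                                    type = "fixed"), B = 300, seed = 7)
  expect_lt(abs(bv$auc$optimism), 0.02)
  expect_equal(bv$auc$corrected, bv$auc$original - bv$auc$optimism)
  # determinism: bit-identical rerun
  bv2 <- bootstrapOptimism(dat, list(outcome = "copd",
                                     predictors = "speedmax",
                                     type = "fixed"), B = 300, seed = 7)
  expect_identical(bv, bv2)
})

test_that("refitted logistic bootstrap shows small positive optimism", {
  set.seed(26)
  dat <- data.frame(copd = rep(c(1, 0), c(12, 34)),
                    speedmax = c(rnorm(12, 760, 85), rnorm(34, 1074, 320)),
                    lesion = c(rnorm(12, 2.4, 0.23), rnorm(34, 1.94, 0.31)))
  bv <- bootstrapOptimism(dat, list(outcome = "copd",
                                    predictors = c("speedmax", "lesion"),
                                    type = "logistic"), B = 200, seed = 3)
  expect_lte(bv$auc$corrected, bv$auc$original + 0.01)
  expect_gte(bv$auc$optimism, -0.02)
  expect_true(all(is.finite(bv$auc$ci95Bca)))
})

test_that("propensity matching respects the caliper deterministically", {
  set.seed(29)
  dat <- data.frame(id = sprintf("P%02d", 1:30),
                    copd = rep(c(1, 0), c(10, 20)),
                    size = c(rnorm(10, 2.4, 0.2), rnorm(20, 2.0, 0.3)))
  m <- propensityMatch(dat, "size", caliper = 0.3)
  expect_true(all(abs(m$pairs$caseCov - m$pairs$controlCov) <= 0.3))
  expect_false(any(duplicated(m$pairs$controlId)))
  expect_identical(m, propensityMatch(dat, "size", caliper = 0.3))

  # identical covariates: the whole smaller group matches at zero distance
  dat2 <- data.frame(id = 1:15, copd = rep(c(1, 0), c(5, 10)),
                     size = rep(2, 15))
  m2 <- propensityMatch(dat2, "size", caliper = 0.3)
  expect_equal(nrow(m2$pairs), 5)
  expect_true(all(m2$pairs$caseCov == m2$pairs$controlCov))

  # disjoint by more than the caliper: no possible pairs
  dat3 <- data.frame(id = 1:10, copd = rep(c(1, 0), each = 5),
                     size = rep(c(3, 1), each = 5))
  expect_error(propensityMatch(dat3, "size", caliper = 0.3), "caliper")
})

test_that("post-hoc power follows the noncentral t exactly", {
  expect_equal(posthocPowerTtest(0, 34, 12), 0.05, tolerance = 1e-10)
  expect_gt(posthocPowerTtest(5, 34, 12), 0.999)

  # Monte-Carlo oracle at the study's configuration (vectorized t-tests)
  set.seed(33)
  B <- 20000
  x <- matrix(rnorm(B * 34, mean = 1.114), B)
  y <- matrix(rnorm(B * 12), B)
  sp2 <- (33 * apply(x, 1, var) + 11 * apply(y, 1, var)) / 44
  tstat <- (rowMeans(x) - rowMeans(y)) / sqrt(sp2 * (1 / 34 + 1 / 12))
  mc <- mean(abs(tstat) > qt(0.975, 44))
  expect_lt(abs(posthocPowerTtest(1.114, 34, 12) - mc), 0.01)
})
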