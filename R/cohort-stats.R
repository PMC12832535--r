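#' Cohen's d from group summary statistics
#'
#' Absolute standardized mean difference with the pooled SD,
#' \code{sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)}. Accepts the
#' rounded printed summaries of a table as well as exact values.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return the effect size d (>= 0).
#' @export
#' @examples
#' cohensD(82.31, 6.41, 34, 58.44, 8.78, 12)  # ~3.373
cohensD <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) .stopf("SDs must be positive")
  if (n1 < 2 || n2 < 2) .stopf("need n >= 2 per group")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  abs(m1 - m2) / sp
}

#' Cohen's d from two samples
#'
#' @param x,y numeric samples (NAs dropped).
#' @return the effect size d.
#' @export
cohensDSamples <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  cohensD(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Normality-routed two-group comparison
#'
#' Shapiro-Wilk on each sample; when both pass at \code{alphaNormal} the
#' groups are compared by a two-sided pooled-variance t-test, otherwise by
#' a two-sided Mann-Whitney U test (normal approximation with continuity
#' correction). The routing decision is reported with the p-value.
#'
#' @param x,y numeric samples, n >= 3 each (NAs dropped: complete-case).
#' @param alphaNormal normality test level, default 0.05.
#' @return list: \code{test} ("t" or "mann-whitney"), \code{p},
#'   \code{statistic}, \code{shapiroP} (both groups).
#' @export
compareContinuous <- function(x, y, alphaNormal = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) .stopf("need n >= 3 per group")
  if (sd(x) == 0 || sd(y) == 0)
    .stopf("degenerate sample: all values identical")
  sw <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  if (all(sw > alphaNormal)) {
    tt <- t.test(x, y, var.equal = TRUE)
    list(test = "t", p = tt$p.value, statistic = unname(tt$statistic),
         shapiroP = sw)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(test = "mann-whitney", p = wt$p.value,
         statistic = unname(wt$statistic), shapiroP = sw)
  }
}

#' Routed 2x2 categorical comparison
#'
#' Fisher's exact test (two-sided, conditional) whenever any expected cell
#' count is at or below 5, otherwise the chi-square test with Yates
#' continuity correction.
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @return list: \code{test} ("fisher" or "chi-square"), \code{p},
#'   \code{expected}.
#' @export
compareCategorical <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stopf("degenerate table: empty margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 5)) {
    list(test = "fisher", p = fisher.test(table)$p.value,
         expected = expected)
  } else {
    list(test = "chi-square",
         p = chisq.test(table, correct = TRUE)$p.value,
         expected = expected)
  }
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks for ties; two-sided p from
#' \code{t = rho sqrt((n-2) / (1 - rho^2))} on n-2 df.
#'
#' @param x,y numeric vectors (pairwise complete cases used), n >= 5.
#' @return list: \code{rho}, \code{p}, \code{n}.
#' @export
spearmanCorr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) .stopf("need n >= 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) .stopf("constant vector: rho undefined")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# DeLong structural components via midranks (exact, O(n log n)): for each
# positive the mean Heaviside score against all negatives (V10), and
# symmetrically V01; ties credited 0.5.
.delongComponents <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)
  R <- rank(c(pos, neg), ties.method = "average")
  v10 <- (R[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (R[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC analysis with Youden cutoff and DeLong confidence interval
#'
#' AUC by the Mann-Whitney statistic (ties credited 0.5, identical to the
#' trapezoidal rule over all thresholds); 95\% CI and the p-value against
#' AUC = 0.5 from the DeLong structural-components variance. The optimal
#' cutoff maximizes Youden's J = sensitivity + specificity - 1 over the
#' observed score values; ties go to the higher sensitivity, then to the
#' lower cutoff. With \code{direction = "auto"} the positive direction is
#' chosen from the group means and recorded (a marker that is lower in the
#' positive class classifies positives as score <= cutoff).
#'
#' @param scores numeric marker values.
#' @param labels logical or 0/1, \code{TRUE} = positive class.
#' @param direction \code{"auto"}, \code{"higher_is_positive"} or
#'   \code{"lower_is_positive"}.
#' @return an \code{ROCResult} list: \code{auc}, \code{aucCi95}, \code{p},
#'   \code{cutoff}, \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv} (percentages), \code{direction}, \code{n}.
#' @export
rocAnalysis <- function(scores, labels,
                        direction = c("auto", "higher_is_positive",
                                      "lower_is_positive")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (!any(labels) || all(labels)) .stopf("both classes must be present")
  if (direction == "auto")
    direction <- if (mean(scores[labels]) >= mean(scores[!labels]))
      "higher_is_positive" else "lower_is_positive"
  s <- if (direction == "lower_is_positive") -scores else scores
  dc <- .delongComponents(s, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  v <- var(dc$v10) / n1 + var(dc$v01) / n0
  se <- sqrt(max(v, 0))
  ci <- pmin(pmax(dc$auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  p <- if (se > 0) 2 * pnorm(-abs((dc$auc - 0.5) / se)) else NA_real_
  # Youden scan over observed cutoffs, in original score units
  cand <- sort(unique(scores))
  pos <- sort(scores[labels]); neg <- sort(scores[!labels])
  if (direction == "lower_is_positive") {
    sens <- findInterval(cand, pos) / n1              # P(pos <= c)
    spec <- 1 - findInterval(cand, neg) / n0          # P(neg >  c)
    tp <- sens * n1; fp <- (1 - spec) * n0
  } else {
    sens <- 1 - findInterval(cand, pos, left.open = TRUE) / n1 # P(pos >= c)
    spec <- findInterval(cand, neg, left.open = TRUE) / n0     # P(neg <  c)
    tp <- sens * n1; fp <- (1 - spec) * n0
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cand[best])]
  tn <- n0 - fp[best]; fn <- n1 - tp[best]
  out <- list(auc = dc$auc, aucCi95 = ci, p = p, cutoff = cand[best],
              sensitivity = 100 * sens[best], specificity = 100 * spec[best],
              ppv = 100 * tp[best] / max(tp[best] + fp[best], 1e-12),
              npv = 100 * tn / max(tn + fn, 1e-12),
              direction = direction, n = c(positive = n1, negative = n0))
  class(out) <- "ROCResult"
  out
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f, p = %.3g), cutoff %.4g (%s)\n  sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
    x$auc, x$aucCi95[1], x$aucCi95[2], x$p, x$cutoff, x$direction,
    x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided comparison of two markers measured on the same subjects, using
#' the paired structural-components covariance estimator. Scores should be
#' oriented so that higher values indicate the positive class.
#'
#' @param scoresA,scoresB paired marker values.
#' @param labels logical or 0/1 positive-class indicator.
#' @return list: \code{aucA}, \code{aucB}, \code{z}, \code{p}.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scoresA) & !is.na(scoresB) & !is.na(labels)
  scoresA <- scoresA[ok]; scoresB <- scoresB[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) .stopf("both classes must be present")
  a <- .delongComponents(scoresA, labels)
  b <- .delongComponents(scoresB, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  v <- var(a$v10 - b$v10) / n1 + var(a$v01 - b$v01) / n0
  if (!is.finite(v) || v <= 1e-16)
    .stopf("degenerate variance: the two markers have identical AUC structure")
  z <- (a$auc - b$auc) / sqrt(v)
  list(aucA = a$auc, aucB = b$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Odds ratio and 95\% Wald confidence interval from a coefficient
#'
#' \code{OR = exp(beta)}; \code{CI = exp(beta +/- 1.96 se)}.
#'
#' @param beta logistic regression coefficient.
#' @param se its standard error (>= 0).
#' @return list: \code{or}, \code{ciLow}, \code{ciHigh}.
#' @export
orFromCoef <- function(beta, se) {
  stopifnot(se >= 0)
  list(or = exp(beta), ciLow = exp(beta - 1.96 * se),
       ciHigh = exp(beta + 1.96 * se))
}

#' Multivariable logistic regression with Wald odds ratios
#'
#' Maximum-likelihood fit (IRLS, convergence tolerance 1e-8) of a binary
#' outcome on one or more predictors, reporting coefficients with standard
#' errors from the observed information, Wald odds ratios with 95\% CIs,
#' the in-sample AUC of the fitted probabilities, and the log loss.
#' Complete separation raises an error rather than returning runaway
#' coefficients.
#'
#' @param predictors numeric matrix or data.frame of predictors.
#' @param outcome logical or 0/1 outcome.
#' @return a \code{LogisticModel} list: \code{coefficients} data.frame
#'   (term, coef, se, z, p, or, orCiLow, orCiHigh), \code{auc},
#'   \code{logLoss}, \code{fit} (the glm object).
#' @export
fitLogisticModel <- function(predictors, outcome) {
  X <- as.data.frame(predictors)
  y <- as.numeric(outcome)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) <= ncol(X) + 1) .stopf("too few observations")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = cbind(X, y = y), family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep && fit$deviance < 1e-4)
    .stopf("separation detected: coefficients diverge")
  sm <- summary(fit)$coefficients
  ors <- orFromCoef(sm[, 1], sm[, 2])
  coefs <- data.frame(term = rownames(sm), coef = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], or = ors$or,
                      orCiLow = ors$ciLow, orCiHigh = ors$ciHigh,
                      row.names = NULL)
  prob <- fitted(fit)
  eps <- 1e-15
  out <- list(coefficients = coefs,
              auc = rocAnalysis(prob, y, "higher_is_positive")$auc,
              logLoss = -mean(y * log(pmax(prob, eps)) +
                                (1 - y) * log(pmax(1 - prob, eps))),
              n = length(y), fit = fit)
  class(out) <- "LogisticModel"
  out
}

#' @export
print.LogisticModel <- function(x, ...) {
  cat(sprintf("Logistic model (n = %d): AUC %.3f, log loss %.4f\n",
              x$n, x$auc, x$logLoss))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Apparent performance of a score against labels: AUC plus sensitivity and
# specificity (%) at the Youden cutoff. Returns the cutoff so it can be
# carried to a test sample.
.scorePerf <- function(scores, labels, direction, cutoff = NULL) {
  r <- rocAnalysis(scores, labels, direction)
  if (is.null(cutoff)) {
    c(auc = r$auc, sens = r$sensitivity, spec = r$specificity,
      cutoff = r$cutoff)
  } else {
    pos <- as.logical(labels); s <- scores
    pred <- if (r$direction == "lower_is_positive") s <= cutoff else
      s >= cutoff
    c(auc = r$auc, sens = 100 * mean(pred[pos]),
      spec = 100 * mean(!pred[!pos]), cutoff = cutoff)
  }
}

.bcaCi <- function(boot, original, jack, level = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) < 10 || sd(boot) == 0)
    return(c(min(boot, original), max(boot, original)))
  z0 <- qnorm(pmin(pmax(mean(boot < original), 1e-6), 1 - 1e-6))
  jm <- mean(jack)
  num <- sum((jm - jack)^3); den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den > 0) num / den else 0
  al <- (1 - level) / 2
  zq <- qnorm(c(al, 1 - al))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  as.numeric(quantile(boot, adj, names = FALSE, type = 7))
}

#' Bootstrap optimism correction of diagnostic performance
#'
#' Harrell's internal-validation procedure: for each of \code{B} bootstrap
#' replicates the model specification is refitted on a resample, its
#' apparent performance on the resample and its test performance on the
#' original sample are recorded, and the optimism is the mean
#' apparent-minus-test difference; the corrected value is the original
#' performance minus the optimism. Sensitivity and specificity (\%) carry
#' each replicate's Youden cutoff to the original sample. Bias-corrected
#' and accelerated (BCa) 95\% intervals are computed over the replicate
#' test performances with jackknife acceleration. Replicates missing a
#' class are redrawn (and counted). Fully reproducible given \code{seed}.
#'
#' @param data data.frame with the model variables.
#' @param modelSpec list: \code{outcome} (column of 0/1 or logical),
#'   \code{predictors} (columns), \code{type} = \code{"logistic"}
#'   (refitted each replicate) or \code{"fixed"} (the single predictor
#'   used as a prespecified score, no fitting -- its optimism is ~0).
#' @param B replicates, default 1000 (>= 100 for CI output).
#' @param seed RNG seed.
#' @return a \code{BootstrapValidation} list with per-metric entries
#'   (\code{auc}, \code{sens}, \code{spec}): original, bootstrapMean,
#'   optimism, corrected, ci95Bca; plus \code{B}, \code{seed},
#'   \code{redraws}.
#' @export
bootstrapOptimism <- function(data, modelSpec, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  y <- as.numeric(data[[modelSpec$outcome]])
  type <- match.arg(modelSpec$type, c("logistic", "fixed"))
  score <- function(d) {
    if (type == "fixed") d[[modelSpec$predictors[1]]]
    else NULL
  }
  fitScore <- function(train, eval) {
    # returns the eval-sample score of the model fitted on train
    if (type == "fixed") {
      list(train = train[[modelSpec$predictors[1]]],
           eval = eval[[modelSpec$predictors[1]]],
           direction = "auto")
    } else {
      f <- fitLogisticModel(train[modelSpec$predictors],
                            train[[modelSpec$outcome]])
      prd <- function(d) as.numeric(
        predict(f$fit, newdata = d[modelSpec$predictors], type = "response"))
      list(train = prd(train), eval = prd(eval),
           direction = "higher_is_positive")
    }
  }
  full <- fitScore(data, data)
  orig <- .scorePerf(full$train, y, full$direction)
  n <- nrow(data)
  set.seed(seed)
  metrics <- c("auc", "sens", "spec")
  apparent <- test <- matrix(NA_real_, B, 3,
                             dimnames = list(NULL, metrics))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    db <- data[idx, , drop = FALSE]
    fb <- tryCatch(fitScore(db, data), error = function(e) NULL)
    if (is.null(fb)) { redraws <- redraws + 1L; next }
    ap <- .scorePerf(fb$train, y[idx], fb$direction)
    te <- .scorePerf(fb$eval, y, fb$direction, cutoff = ap["cutoff"])
    apparent[b, ] <- ap[metrics]
    test[b, ] <- te[metrics]
  }
  keep <- stats::complete.cases(apparent)
  apparent <- apparent[keep, , drop = FALSE]
  test <- test[keep, , drop = FALSE]
  jack <- vapply(seq_len(n), function(i) {
    fj <- fitScore(data[-i, , drop = FALSE], data[-i, , drop = FALSE])
    .scorePerf(fj$train, y[-i], fj$direction)[metrics]
  }, numeric(3))
  out <- lapply(seq_along(metrics), function(k) {
    opt <- mean(apparent[, k] - test[, k])
    list(original = unname(orig[metrics[k]]),
         bootstrapMean = mean(apparent[, k]),
         optimism = opt,
         corrected = unname(orig[metrics[k]]) - opt,
         ci95Bca = if (nrow(test) >= 100)
           .bcaCi(test[, k], unname(orig[metrics[k]]), jack[k, ])
         else c(NA_real_, NA_real_))
  })
  names(out) <- metrics
  out$B <- B; out$seed <- seed; out$redraws <- redraws
  out$nReplicatesUsed <- nrow(test)
  class(out) <- "BootstrapValidation"
  out
}

#' @export
print.BootstrapValidation <- function(x, ...) {
  cat(sprintf("Bootstrap optimism correction (B = %d, seed = %d)\n",
              x$B, x$seed))
  for (m in c("auc", "sens", "spec")) {
    e <- x[[m]]
    cat(sprintf(
      "  %-4s original %.3f, boot mean %.3f, optimism %+.4f, corrected %.3f, BCa95 [%.3f, %.3f]\n",
      m, e$original, e$bootstrapMean, e$optimism, e$corrected,
      e$ci95Bca[1], e$ci95Bca[2]))
  }
  invisible(x)
}

#' Caliper-constrained 1:1 propensity-score matching
#'
#' Propensity of case status is modeled by logistic regression on the
#' matching covariate; cases are processed in descending propensity and
#' greedily paired to the nearest-propensity unused control, rejecting any
#' pair whose covariate difference exceeds the caliper. Deterministic:
#' ties break by covariate distance, then input order.
#'
#' @param data data.frame with an id column, a logical/0-1 case indicator
#'   and the matching covariate.
#' @param covariate covariate column name (e.g. lesion size in cm).
#' @param case case-indicator column name.
#' @param id id column name.
#' @param caliper maximum absolute covariate difference, default 0.3.
#' @return a \code{MatchedCohort} list: \code{pairs} data.frame
#'   (caseId, controlId, caseCov, controlCov), \code{caliper},
#'   \code{unmatched} (case ids left unpaired).
#' @export
propensityMatch <- function(data, covariate, case = "copd", id = "id",
                            caliper = 0.3) {
  cc <- !is.na(data[[covariate]]) & !is.na(data[[case]])
  data <- data[cc, , drop = FALSE]
  trt <- as.logical(data[[case]])
  if (!any(trt) || all(trt)) .stopf("both groups must be nonempty")
  ps <- fitted(glm(trt ~ data[[covariate]], family = binomial()))
  cases <- which(trt)[order(ps[trt], decreasing = TRUE)]
  controls <- which(!trt)
  used <- rep(FALSE, length(controls))
  pairs <- list(); unmatched <- c()
  for (i in cases) {
    dps <- abs(ps[controls] - ps[i])
    dcov <- abs(data[[covariate]][controls] - data[[covariate]][i])
    elig <- !used & dcov <= caliper
    if (!any(elig)) { unmatched <- c(unmatched, data[[id]][i]); next }
    cand <- which(elig)
    cand <- cand[order(dps[cand], dcov[cand], cand)]
    j <- cand[1]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      caseId = data[[id]][i], controlId = data[[id]][controls[j]],
      caseCov = data[[covariate]][i],
      controlCov = data[[covariate]][controls[j]])
  }
  if (!length(pairs)) .stopf("no pairs satisfy the %.3g caliper", caliper)
  out <- list(pairs = do.call(rbind, pairs), caliper = caliper,
              unmatched = unmatched)
  class(out) <- "MatchedCohort"
  out
}

#' @export
print.MatchedCohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d pairs (caliper %.3g), %d unmatched case(s)\n",
              nrow(x$pairs), x$caliper, length(x$unmatched)))
  invisible(x)
}

#' Post-hoc power of a two-sided two-sample t-test
#'
#' Exact noncentral-t power at effect size d:
#' \code{ncp = d sqrt(n1 n2 / (n1 + n2))}, df = n1 + n2 - 2.
#'
#' @param d Cohen's d (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided level, default 0.05.
#' @return power in [alpha, 1].
#' @export
posthocPowerTtest <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}
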