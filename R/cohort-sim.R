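# Truncated-normal utilities: quantile transform for the copula, and
# moment matching so that the truncated distribution reproduces a target
# mean/SD exactly (bounded variables such as pack-years or the GOLD-split
# FEV1/FVC ratio would otherwise drift from the printed summaries).

.qtnorm <- function(u, mu, sigma, a, b) {
  pa <- pnorm(a, mu, sigma); pb <- pnorm(b, mu, sigma)
  qnorm(pa + u * (pb - pa), mu, sigma)
}

.tnormMoments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  t1 <- if (is.finite(al)) al * da else 0
  t2 <- if (is.finite(be)) be * db else 0
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

.tnormMomentMatch <- function(m, s, a, b) {
  # negligible truncation: use the target parameters directly
  if ((!is.finite(a) || a < m - 6 * s) && (!is.finite(b) || b > m + 6 * s))
    return(c(mu = m, sigma = s))
  obj <- function(p) {
    mm <- .tnormMoments(p[1], exp(p[2]), a, b)
    (mm[1] - m)^2 / s^2 + (mm[2] - s)^2 / s^2
  }
  fit <- optim(c(m, log(s)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6)
    .stopf("cannot moment-match truncated normal (target %.3g +/- %.3g on [%.3g, %.3g])",
           m, s, a, b)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# nearest positive-definite repair by eigenvalue clipping + unit-diagonal
# rescale
.nearestPd <- function(S, eps = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > eps) return(S)
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  D <- 1 / sqrt(diag(S2))
  S2 <- S2 * outer(D, D)
  dimnames(S2) <- dimnames(S)
  S2
}

# per-group marginal summaries (mean, SD, truncation bounds) for every
# cohort variable; the printed two-group summaries of the study population
.cohortMarginals <- function() {
  v <- function(var, mN, sN, mC, sC, lo, hi, loC = lo, hiC = hi)
    data.frame(var = var, meanNormal = mN, sdNormal = sN, meanCopd = mC,
               sdCopd = sC, loNormal = lo, hiNormal = hi, loCopd = loC,
               hiCopd = hiC)
  rbind(
    v("age",        67.29,  9.52,  72.08,  6.08,  40,    85),
    v("height",      1.70,  0.06,   1.66,  0.06,   1.40,  2.00),
    v("weight",     66.52, 10.62,  60.21,  7.90,  35,   120),
    v("bmi",        23.16,  3.29,  21.86,  2.75,  14,    40),
    v("pack_years", 15.15, 18.11,  19.58, 21.04,   0,   150),
    v("lesion_size", 1.94,  0.31,   2.40,  0.23,   0.5,   3.0),
    v("fvc",         2.88,  0.73,   1.92,  0.55,   0.5,   8),
    v("fev1",        2.37,  0.63,   1.13,  0.40,   0.3,   6),
    # GOLD split: normal >= 70%, COPD < 70%
    v("fev1_fvc",   82.31,  6.41,  58.44,  8.78,  70,   100, 20, 70),
    v("pef",         5.61,  1.80,   3.22,  1.07,   0.5,  15),
    v("mef50",       2.96,  1.17,   0.68,  0.35,   0.05,  8),
    v("psmax",      26.32,  8.71,  22.70,  6.58,   0,    60),
    v("psmean",      2.51,  0.88,   2.14,  0.54,   0,     8),
    v("speedmax", 1074.19, 319.68, 763.22, 85.22,  50, 2500),
    v("pi15",     -844.68, 50.86, -890.92, 42.57, -1000, -600),
    v("laa",         3.23,  1.43,   7.30,  4.18,   0,    40),
    v("mld",      -767.79, 68.58, -889.23, 77.02, -1000, -500))
}

# fixed within-group latent (Spearman-scale) correlations among the
# continuous variables, beyond the calibrated Speedmax targets; plausible
# physiologic structure, identical in both groups
.cohortBaseCorr <- function(vars) {
  S <- diag(length(vars))
  dimnames(S) <- list(vars, vars)
  set2 <- function(a, b, r) {
    S[a, b] <<- r; S[b, a] <<- r
  }
  set2("fvc", "fev1", 0.75);      set2("fvc", "pef", 0.50)
  set2("fvc", "mef50", 0.40);     set2("fvc", "fev1_fvc", 0.10)
  set2("fev1", "pef", 0.60);      set2("fev1", "mef50", 0.65)
  set2("fev1", "fev1_fvc", 0.45); set2("pef", "mef50", 0.55)
  set2("fev1_fvc", "mef50", 0.60); set2("fev1_fvc", "pef", 0.30)
  set2("height", "fvc", 0.45);    set2("height", "fev1", 0.35)
  set2("height", "weight", 0.40); set2("weight", "bmi", 0.75)
  set2("height", "bmi", -0.15);   set2("age", "fev1", -0.30)
  set2("age", "fvc", -0.25);      set2("age", "height", -0.15)
  set2("psmax", "psmean", 0.60);  set2("psmax", "speedmax", 0.30)
  set2("psmean", "speedmax", 0.30)
  set2("mld", "laa", -0.60);      set2("mld", "pi15", 0.70)
  set2("laa", "pi15", -0.60);     set2("laa", "fev1_fvc", -0.30)
  S
}

#' Specification of a simulated two-group cohort
#'
#' Marginals are per-group truncated normals moment-matched to the study's
#' printed group means/SDs (Tables of demographics, spirometry, strain and
#' densitometry), joined by a Gaussian copula. The headline rank
#' correlations of Speedmax with FEV1/FVC, FEV1, MEF50 and FVC are pooled
#' (both groups together) quantities, so the within-group copula
#' correlation is calibrated at generation time (deterministic
#' common-random-number bisection) until the pooled Spearman correlation at
#' the requested group sizes matches the target. COPD/normal labels are
#' consistent with the drawn FEV1/FVC (GOLD split at 70\%) by construction.
#'
#' @param nNormal,nCopd group sizes, default 34 and 12.
#' @param targetSpearman named numeric: pooled Spearman targets for
#'   Speedmax against \code{fev1_fvc}, \code{fev1}, \code{mef50},
#'   \code{fvc}; defaults 0.533, 0.445, 0.525, 0.351.
#' @param binaryRates named list of per-group event rates for the binary
#'   traits (male, smoker, cough, sputum) and the mMRC >= 2 dyspnea rate.
#' @param calibratePooled when \code{TRUE} (default) the
#'   \code{targetSpearman} values are pooled-cohort targets and the
#'   within-group copula correlation is calibrated to meet them; when
#'   \code{FALSE} they are used directly as within-group latent
#'   correlations (e.g. zero = within-group independence). The pooled
#'   correlation of a two-group mixture is never zero while the group
#'   means differ, so exact independence statements are within-group
#'   statements.
#' @param seed RNG seed.
#' @return a \code{CohortSpec} list.
#' @export
cohortSpec <- function(nNormal = 34, nCopd = 12,
                       targetSpearman = c(fev1_fvc = 0.533, fev1 = 0.445,
                                          mef50 = 0.525, fvc = 0.351),
                       binaryRates = list(
                         male = c(normal = 0.794, copd = 0.917),
                         smoker = c(normal = 0.441, copd = 0.500),
                         cough = c(normal = 0.412, copd = 0.833),
                         sputum = c(normal = 0.353, copd = 0.833),
                         dyspnea = c(normal = 0.0, copd = 0.75)),
                       calibratePooled = TRUE, seed = 1) {
  spec <- list(nNormal = as.integer(nNormal), nCopd = as.integer(nCopd),
               targetSpearman = targetSpearman, binaryRates = binaryRates,
               calibratePooled = isTRUE(calibratePooled),
               marginals = .cohortMarginals(), seed = seed)
  class(spec) <- "CohortSpec"
  spec
}

# draw the continuous block for both groups given the latent correlation
# matrix; z is an optional pre-drawn standard-normal matrix (for the
# calibration's common random numbers)
.drawContinuous <- function(spec, L, zAll) {
  marg <- spec$marginals
  vars <- marg$var
  nN <- nrow(zAll$normal); nC <- nrow(zAll$copd)
  out <- list()
  for (grp in c("normal", "copd")) {
    z <- zAll[[grp]] %*% t(L)
    u <- pnorm(z)
    df <- as.data.frame(matrix(NA_real_, nrow(z), length(vars)))
    names(df) <- vars
    for (j in seq_along(vars)) {
      mrow <- marg[j, ]
      m <- if (grp == "normal") mrow$meanNormal else mrow$meanCopd
      s <- if (grp == "normal") mrow$sdNormal else mrow$sdCopd
      lo <- if (grp == "normal") mrow$loNormal else mrow$loCopd
      hi <- if (grp == "normal") mrow$hiNormal else mrow$hiCopd
      if (vars[j] == "pack_years") {
        # zero-inflated: only smokers accumulate pack-years, so the
        # printed mean/SD describe a mixture with mass at zero (its CV
        # exceeds what any truncated normal can reach). Draw the positive
        # part here with exact mixture moments; the smoker indicator
        # multiplies in later.
        pSmoke <- spec$binaryRates$smoker[[grp]]
        mPos <- m / pSmoke
        s2Pos <- (s^2 + m^2) / pSmoke - mPos^2
        if (s2Pos <= 0) .stopf("pack-years moments infeasible")
        mm <- .tnormMomentMatch(mPos, sqrt(s2Pos), lo, hi)
      } else {
        mm <- .tnormMomentMatch(m, s, lo, hi)
      }
      df[[j]] <- .qtnorm(u[, j], mm[1], mm[2], lo, hi)
    }
    out[[grp]] <- df
  }
  out
}

# calibrate the latent Speedmax-vs-target correlations so the POOLED
# Spearman matches the targets at the spec's group mix
.calibrateSpeedmax <- function(spec) {
  marg <- spec$marginals
  nInt <- 1500L
  frac <- c(normal = spec$nNormal, copd = spec$nCopd) /
    (spec$nNormal + spec$nCopd)
  nG <- pmax(200L, round(2 * nInt * frac))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  set.seed(202401L)  # internal common random numbers; fixed by design
  zs <- list(normal = matrix(rnorm(nG[1] * 2), nG[1]),
             copd = matrix(rnorm(nG[2] * 2), nG[2]))
  res <- numeric(length(spec$targetSpearman))
  names(res) <- names(spec$targetSpearman)
  for (v in names(spec$targetSpearman)) {
    mv <- marg[marg$var == v, ]
    ms <- marg[marg$var == "speedmax", ]
    pooled <- function(s) {
      val <- function(z, m, lo, hi, mu, sd)
        .qtnorm(pnorm(z), m[1], m[2], lo, hi)
      xs <- c(); ys <- c()
      for (grp in c("normal", "copd")) {
        z <- zs[[grp]]
        z2 <- s * z[, 1] + sqrt(1 - s^2) * z[, 2]
        if (grp == "normal") {
          mmS <- .tnormMomentMatch(ms$meanNormal, ms$sdNormal, ms$loNormal,
                                   ms$hiNormal)
          mmV <- .tnormMomentMatch(mv$meanNormal, mv$sdNormal, mv$loNormal,
                                   mv$hiNormal)
          xs <- c(xs, .qtnorm(pnorm(z[, 1]), mmS[1], mmS[2], ms$loNormal,
                              ms$hiNormal))
          ys <- c(ys, .qtnorm(pnorm(z2), mmV[1], mmV[2], mv$loNormal,
                              mv$hiNormal))
        } else {
          mmS <- .tnormMomentMatch(ms$meanCopd, ms$sdCopd, ms$loCopd,
                                   ms$hiCopd)
          mmV <- .tnormMomentMatch(mv$meanCopd, mv$sdCopd, mv$loCopd,
                                   mv$hiCopd)
          xs <- c(xs, .qtnorm(pnorm(z[, 1]), mmS[1], mmS[2], ms$loCopd,
                              ms$hiCopd))
          ys <- c(ys, .qtnorm(pnorm(z2), mmV[1], mmV[2], mv$loCopd,
                              mv$hiCopd))
        }
      }
      cor(rank(xs), rank(ys))
    }
    target <- spec$targetSpearman[[v]]
    f <- function(s) pooled(s) - target
    lo <- -0.985; hi <- 0.985
    if (f(lo) > 0 || f(hi) < 0)
      .stopf("pooled Spearman target %.3g for %s is infeasible", target, v)
    res[v] <- uniroot(f, c(lo, hi), tol = 1e-3)$root
  }
  res
}

#' Simulate a two-group cohort with study-like structure
#'
#' Draws \code{nNormal + nCopd} patient records whose per-group marginal
#' means/SDs match the printed study summaries and whose pooled Speedmax
#' rank correlations with spirometry match the stated targets (see
#' \code{\link{cohortSpec}}). Binary traits are drawn at the per-group
#' rates; mMRC grades respect the dyspnea (>= 2) rate. Deterministic given
#' the spec seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return a data.frame (one row per patient) with columns \code{id},
#'   \code{group}, \code{copd}, the binary traits, \code{mmrc},
#'   \code{dyspnea}, \code{lesion_lobe} and all continuous variables.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  marg <- spec$marginals
  vars <- marg$var
  base <- .cohortBaseCorr(vars)[vars, vars]
  cal <- if (spec$calibratePooled) .calibrateSpeedmax(spec) else
    2 * sin(pi * unlist(spec$targetSpearman) / 6)
  # latent (copula) scale: convert the fixed Spearman entries, then insert
  # the calibrated latent Speedmax entries verbatim
  lat <- 2 * sin(pi * base / 6)
  diag(lat) <- 1
  for (v in names(cal)) {
    lat["speedmax", v] <- cal[[v]]
    lat[v, "speedmax"] <- cal[[v]]
  }
  lat <- .nearestPd(lat)
  L <- chol(lat)
  set.seed(spec$seed)
  zAll <- list(normal = matrix(rnorm(spec$nNormal * length(vars)),
                               spec$nNormal),
               copd = matrix(rnorm(spec$nCopd * length(vars)), spec$nCopd))
  cont <- .drawContinuous(spec, t(L), zAll)  # z %*% t(t(L)) = z %*% L
  br <- spec$binaryRates
  mk <- function(grp, n) {
    df <- cont[[grp]]
    df$group <- grp
    df$copd <- as.integer(grp == "copd")
    for (b in c("male", "smoker", "cough", "sputum"))
      df[[b]] <- rbinom(n, 1, br[[b]][[grp]])
    df$pack_years <- df$pack_years * df$smoker
    dys <- rbinom(n, 1, br$dyspnea[[grp]])
    # grade within the dyspnea strata: 0/1 below, 2-4 above
    df$mmrc <- ifelse(dys == 1, sample(2:4, n, TRUE, c(0.5, 0.35, 0.15)),
                      sample(0:1, n, TRUE, c(0.65, 0.35)))
    df$dyspnea <- dys
    df$lesion_lobe <- sample(c("upper", "lower"), n, TRUE)
    df
  }
  out <- rbind(mk("normal", spec$nNormal), mk("copd", spec$nCopd))
  out$id <- sprintf("P%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "group", "copd", "male", "age", "height", "weight", "bmi",
          "smoker", "pack_years", "lesion_size", "lesion_lobe", "cough",
          "sputum", "mmrc", "dyspnea", "fvc", "fev1", "fev1_fvc", "pef",
          "mef50", "psmax", "psmean", "speedmax", "pi15", "laa", "mld")]
}
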