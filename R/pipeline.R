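#' Pipeline configuration with the analysis defaults
#'
#' Collects every stage parameter in one validated object. Defaults are the
#' analysis settings used throughout the package: -400 HU segmentation
#' threshold, 1000-voxel component floor, 5-voxel closing radius, the
#' seven-parameter Farneback settings of \code{\link{flowParams}}, 2 mm TRE
#' gate, -950 HU LAA threshold, Perc15, 1000 bootstrap replicates, 0.3 cm
#' matching caliper. \code{resampleFactor} (default 0.5) is the
#' preprocessing downsample applied to full-resolution clinical scans; set
#' it to 1 for data already at analysis resolution (e.g. the phantoms).
#'
#' @param thresholdHu segmentation threshold, HU.
#' @param minSizeVoxels component size floor.
#' @param closeRadiusVoxels closing ball radius, voxels.
#' @param flow a \code{\link{flowParams}} object.
#' @param dt inter-phase interval, seconds.
#' @param treThresholdMm TRE acceptance gate, mm.
#' @param laaThresholdHu LAA threshold, HU.
#' @param percentile densitometry percentile.
#' @param rocDirection ROC direction policy.
#' @param bootstrapB bootstrap replicates.
#' @param caliper propensity-matching caliper (covariate units).
#' @param resampleFactor preprocessing resampling factor.
#' @param miBins mutual-information histogram bins.
#' @param scaleMode strain summary scaling, see \code{\link{strainSummary}}.
#' @param flowSmoothSigmaVox displacement-field regularization, see
#'   \code{\link{smoothDisplacementField}}.
#' @param seed RNG seed for the stochastic analyses.
#' @return a \code{PipelineConfig} list with a provenance hash.
#' @export
pipelineConfig <- function(thresholdHu = -400, minSizeVoxels = 1000,
                           closeRadiusVoxels = 5, flow = flowParams(),
                           dt = 2.0, treThresholdMm = 2.0,
                           laaThresholdHu = -950, percentile = 15,
                           rocDirection = "auto", bootstrapB = 1000,
                           caliper = 0.3, resampleFactor = 0.5,
                           miBins = 32, scaleMode = "paper_mm",
                           flowSmoothSigmaVox = c(1, 2, 2),
                           seed = 20240315) {
  cfg <- list(thresholdHu = thresholdHu, minSizeVoxels = minSizeVoxels,
              closeRadiusVoxels = closeRadiusVoxels, flow = flow, dt = dt,
              treThresholdMm = treThresholdMm,
              laaThresholdHu = laaThresholdHu, percentile = percentile,
              rocDirection = rocDirection, bootstrapB = bootstrapB,
              caliper = caliper, resampleFactor = resampleFactor,
              miBins = miBins, scaleMode = scaleMode,
              flowSmoothSigmaVox = flowSmoothSigmaVox, seed = seed)
  cfg$version <- as.character(utils::packageVersion("lungstrain"))
  cfg$hash <- configHash(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' FNV-1a hash of a serialized R object
#'
#' Used for report provenance and determinism checks.
#'
#' @param x any serializable object.
#' @return an 8-hex-digit string.
#' @export
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full per-patient strain pipeline
#'
#' End-expiration is the registration reference: both phases are segmented,
#' EI is aligned to EE by centroid + mutual-information translation, the
#' TRE gate is evaluated at the supplied landmarks (after translation and
#' flow), slice-wise Farneback flow yields the dense displacement field,
#' strain tensors and the PSmax/PSmean/Speedmax summary are computed over
#' the EE lung mask (the registration translation, strain-free but real
#' motion, is restored for the speed statistic), and densitometry is
#' measured on the original EI volume. Any stage failure or a failed TRE
#' gate yields a report with the exclusion flag set -- no partial silent
#' results.
#'
#' @param ei,ee \linkS4class{CTVolume}s (end-inspiration, end-expiration).
#' @param config a \code{\link{pipelineConfig}}.
#' @param landmarksEI,landmarksEE optional paired landmark data.frames
#'   (id/z/y/x mm) for the TRE gate; omitted = gate not evaluated.
#' @return a \code{PatientReport} list: \code{strain}, \code{densitometry},
#'   \code{tre}, \code{shift}, \code{excluded}, \code{exclusionReason},
#'   \code{log} (stage data.frame), \code{configHash}.
#' @export
runPatient <- function(ei, ee, config = pipelineConfig(),
                       landmarksEI = NULL, landmarksEE = NULL) {
  log <- data.frame(stage = character(), status = character(),
                    detail = character())
  note <- function(stage, status, detail = "")
    log <<- rbind(log, data.frame(stage = stage, status = status,
                                  detail = detail))
  fail <- function(stage, reason) {
    note(stage, "error", reason)
    structure(list(strain = NULL, densitometry = NULL, tre = NULL,
                   shift = NULL, excluded = TRUE, exclusionReason = reason,
                   log = log, configHash = config$hash),
              class = "PatientReport")
  }
  run <- function(stage, expr) {
    r <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           msg = conditionMessage(e)))
    if (r$ok) note(stage, "ok")
    r
  }

  if (!isTRUE(all.equal(ei@spacing, ee@spacing)) ||
      !identical(dim(ei@voxels), dim(ee@voxels)))
    return(fail("input", "EI/EE geometry mismatch"))

  if (config$resampleFactor != 1) {
    r <- run("resample", list(
      ei = resampleVolume(ei, config$resampleFactor),
      ee = resampleVolume(ee, config$resampleFactor)))
    if (!r$ok) return(fail("resample", r$msg))
    ei <- r$value$ei; ee <- r$value$ee
  }

  r <- run("segment", list(
    ei = segmentLungs(ei, config$thresholdHu, config$minSizeVoxels,
                      config$closeRadiusVoxels),
    ee = segmentLungs(ee, config$thresholdHu, config$minSizeVoxels,
                      config$closeRadiusVoxels)))
  if (!r$ok) return(fail("segment", r$msg))
  maskEI <- r$value$ei; maskEE <- r$value$ee

  r <- run("register", {
    t0 <- centroidTranslation(maskEE, maskEI)
    refineTranslationMi(ee, ei, init = t0, bins = config$miBins,
                        mask = maskEE)
  })
  if (!r$ok) return(fail("register", r$msg))
  shift <- r$value$shift
  eiAligned <- applyTranslation(ei, shift)

  r <- run("flow", {
    zAny <- which(apply(maskEE@mask, 1, sum) > 0)
    sl <- max(1, min(zAny) - 1):min(dim(ee@voxels)[1], max(zAny) + 1)
    farnebackFlow(eiAligned, ee, config$flow, dt = config$dt,
                  sliceRange = sl)
  })
  if (!r$ok) return(fail("flow", r$msg))
  disp <- smoothDisplacementField(r$value, config$flowSmoothSigmaVox)

  tre <- NULL
  if (!is.null(landmarksEI) && !is.null(landmarksEE)) {
    r <- run("tre", {
      moved <- landmarksEI
      moved$z <- moved$z + shift[1]
      moved$y <- moved$y + shift[2]
      moved$x <- moved$x + shift[3]
      # add the local flow at each (aligned) landmark
      d <- dim(disp@uy)
      zi <- pmin(pmax(round(moved$z / ee@spacing[1] + 1), 1), d[1])
      for (i in seq_len(nrow(moved))) {
        yi <- moved$y[i] / ee@spacing[2] + 1
        xi <- moved$x[i] / ee@spacing[3] + 1
        moved$y[i] <- moved$y[i] + .bilinear(disp@uy[zi[i], , ], yi, xi)
        moved$x[i] <- moved$x[i] + .bilinear(disp@ux[zi[i], , ], yi, xi)
      }
      computeTre(landmarksEE, moved, config$treThresholdMm)
    })
    if (!r$ok) return(fail("tre", r$msg))
    tre <- r$value
    if (!tre$pass) {
      rep <- fail("tre-gate", sprintf(
        "TRE gate failed: max %.2f mm >= %.2f mm; case excluded from analysis",
        tre$maxError, config$treThresholdMm))
      rep$tre <- tre
      return(rep)
    }
  }

  r <- run("strain", {
    tens <- strainTensors(disp)
    eigs <- principalStrains(tens)
    strainSummary(eigs, disp, maskEE, scaleMode = config$scaleMode,
                  baselineShift = shift[2:3])
  })
  if (!r$ok) return(fail("strain", r$msg))
  strain <- r$value

  r <- run("densitometry",
           densitometry(ei, maskEI, config$laaThresholdHu,
                        config$percentile))
  if (!r$ok) return(fail("densitometry", r$msg))

  structure(list(strain = strain, densitometry = r$value, tre = tre,
                 shift = shift, excluded = FALSE,
                 exclusionReason = NA_character_, log = log,
                 configHash = config$hash),
            class = "PatientReport")
}

#' @export
print.PatientReport <- function(x, ...) {
  if (x$excluded) {
    cat("PatientReport: EXCLUDED --", x$exclusionReason, "\n")
  } else {
    cat("PatientReport (config", x$configHash, ")\n")
    show(x$strain)
    print(x$densitometry)
    if (!is.null(x$tre)) print(x$tre)
  }
  invisible(x)
}

.requiredCohortCols <- c("id", "group", "copd", "speedmax", "psmax",
                         "psmean", "lesion_size", "fvc", "fev1",
                         "fev1_fvc", "pef", "mef50")

#' Cohort-level statistical analysis bundle
#'
#' Reproduces the study's statistical workflow on a cohort table:
#' group comparisons (normality-routed tests with Cohen's d for continuous
#' variables, routed Fisher/chi-square for binary traits), the pooled
#' Spearman correlation table of strain parameters against spirometry, ROC
#' analyses with Youden cutoffs for the three strain parameters plus
#' DeLong comparisons against Speedmax, bootstrap optimism correction of
#' the Speedmax logistic model, univariable and lesion-size-adjusted
#' logistic models, the lesion-size propensity-matched sensitivity
#' analysis, and post-hoc power for the Speedmax contrast. Missing values
#' are handled complete-case per analysis.
#'
#' @param cohort data.frame like \code{\link{simulateCohort}} output.
#' @param config a \code{\link{pipelineConfig}} (bootstrap B, seed,
#'   caliper, ROC direction).
#' @return a \code{CohortReport} list of per-section results.
#' @export
runCohort <- function(cohort, config = pipelineConfig()) {
  miss <- setdiff(.requiredCohortCols, names(cohort))
  if (length(miss))
    .stopf("cohort table lacks required columns: %s",
           paste(miss, collapse = ", "))
  copd <- as.logical(cohort$copd)
  if (!any(copd) || all(copd)) .stopf("both groups must be nonempty")

  contVars <- intersect(c("age", "height", "weight", "bmi", "pack_years",
                          "lesion_size", "fvc", "fev1", "fev1_fvc", "pef",
                          "mef50", "psmax", "psmean", "speedmax", "pi15",
                          "laa", "mld"), names(cohort))
  groupComparison <- do.call(rbind, lapply(contVars, function(v) {
    x <- cohort[[v]][!copd]; y <- cohort[[v]][copd]
    cmp <- compareContinuous(x, y)
    data.frame(variable = v,
               meanNormal = mean(x, na.rm = TRUE),
               sdNormal = sd(x, na.rm = TRUE),
               meanCopd = mean(y, na.rm = TRUE),
               sdCopd = sd(y, na.rm = TRUE),
               test = cmp$test, p = cmp$p,
               cohensD = cohensDSamples(x, y))
  }))

  catVars <- intersect(c("male", "smoker", "cough", "sputum", "dyspnea"),
                       names(cohort))
  categorical <- do.call(rbind, lapply(catVars, function(v) {
    tab <- table(factor(cohort[[v]] > 0, c(FALSE, TRUE)),
                 factor(copd, c(FALSE, TRUE)))
    cmp <- compareCategorical(tab)
    data.frame(variable = v,
               rateNormal = mean(cohort[[v]][!copd] > 0, na.rm = TRUE),
               rateCopd = mean(cohort[[v]][copd] > 0, na.rm = TRUE),
               test = cmp$test, p = cmp$p)
  }))

  strainVars <- c("psmax", "psmean", "speedmax")
  pftVars <- c("fev1_fvc", "fev1", "mef50", "fvc")
  correlation <- do.call(rbind, lapply(strainVars, function(sv) {
    do.call(rbind, lapply(pftVars, function(pv) {
      sc <- spearmanCorr(cohort[[sv]], cohort[[pv]])
      data.frame(strain = sv, pft = pv, rho = sc$rho, p = sc$p, n = sc$n)
    }))
  }))

  roc <- lapply(setNames(strainVars, strainVars), function(v)
    rocAnalysis(cohort[[v]], copd, config$rocDirection))
  # orient all markers so higher = COPD before the paired AUC comparisons
  orient <- function(v)
    if (roc[[v]]$direction == "lower_is_positive") -cohort[[v]]
    else cohort[[v]]
  delong <- list(
    speedmaxVsPsmax = delongTest(orient("speedmax"), orient("psmax"), copd),
    speedmaxVsPsmean = delongTest(orient("speedmax"), orient("psmean"),
                                  copd))

  bootstrap <- bootstrapOptimism(
    cohort, list(outcome = "copd", predictors = "speedmax",
                 type = "logistic"),
    B = config$bootstrapB, seed = config$seed)

  logistic <- list(
    model1 = fitLogisticModel(cohort["speedmax"], cohort$copd),
    model2 = fitLogisticModel(cohort[c("speedmax", "lesion_size")],
                              cohort$copd))

  matchRes <- propensityMatch(cohort, covariate = "lesion_size",
                              case = "copd", id = "id",
                              caliper = config$caliper)
  mi <- match(matchRes$pairs$caseId, cohort$id)
  mj <- match(matchRes$pairs$controlId, cohort$id)
  matched <- do.call(rbind, lapply(c("lesion_size", "speedmax"),
                                   function(v) {
    xc <- cohort[[v]][mi]; xn <- cohort[[v]][mj]
    tt <- t.test(xc, xn, paired = TRUE)
    data.frame(variable = v, meanCopd = mean(xc), sdCopd = sd(xc),
               meanNormal = mean(xn), sdNormal = sd(xn),
               pairedP = tt$p.value, cohensD = cohensDSamples(xc, xn))
  }))

  dS <- groupComparison$cohensD[groupComparison$variable == "speedmax"]
  power <- posthocPowerTtest(dS, sum(!copd), sum(copd))

  structure(list(groupComparison = groupComparison,
                 categorical = categorical, correlation = correlation,
                 roc = roc, delong = delong, bootstrap = bootstrap,
                 logistic = logistic, match = matchRes,
                 matchedComparison = matched, power = power,
                 n = c(normal = sum(!copd), copd = sum(copd)),
                 configHash = config$hash),
            class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat(sprintf("CohortReport: n = %d normal / %d COPD\n",
              x$n["normal"], x$n["copd"]))
  cat("\nGroup comparison (continuous):\n")
  print(x$groupComparison, digits = 4)
  cat("\nSpearman correlations (pooled):\n")
  print(x$correlation, digits = 3)
  cat("\nROC (Speedmax):\n"); print(x$roc$speedmax)
  cat("\n"); print(x$bootstrap)
  cat("\nLogistic models:\n")
  print(x$logistic$model1); print(x$logistic$model2)
  cat("\n"); print(x$match)
  cat(sprintf("\nPost-hoc power (Speedmax contrast): %.3f\n", x$power))
  invisible(x)
}

#' Write a cohort or patient report as JSON
#'
#' @param report a \code{CohortReport} or \code{PatientReport}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReportJson <- function(report, path) {
  clean <- rapply(unclass(report), function(x) x, how = "replace")
  strip <- function(x) {
    if (inherits(x, "glm")) return(NULL)
    if (isS4(x)) {
      sl <- lapply(slotNames(x), function(s) slot(x, s))
      names(sl) <- slotNames(x)
      return(sl)
    }
    if (is.list(x)) {
      out <- lapply(x, strip)
      return(out[!vapply(out, is.null, logical(1))])
    }
    x
  }
  jsonlite::write_json(strip(clean), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  invisible(path)
}
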