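#' Centroid-difference translation between two lung masks
#'
#' Initial rigid estimate: the shift (mm, \code{(z, y, x)}) that moves the
#' moving mask's centre of mass onto the fixed mask's,
#' \code{shift = centroid(fixed) - centroid(moving)}.
#'
#' @param fixedMask,movingMask nonempty \linkS4class{LungMask} objects.
#' @return numeric(3) shift in mm.
#' @export
centroidTranslation <- function(fixedMask, movingMask) {
  cen <- function(m) {
    if (sum(m@mask) == 0) .stopf("empty mask has no centroid")
    idx <- which(m@mask > 0, arr.ind = TRUE)
    m@origin + (colMeans(idx) - 1) * m@spacing
  }
  unname(cen(fixedMask) - cen(movingMask))
}

#' Apply a rigid translation to a CT volume
#'
#' \code{output(x) = input(x - t)}: image content moves by \code{+t}.
#' Out-of-range samples are filled with -1000 HU (air).
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param t numeric(3) translation in mm, \code{(z, y, x)}.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return the translated \linkS4class{CTVolume}.
#' @export
applyTranslation <- function(vol, t, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(all(is.finite(t)), length(t) == 3L)
  if (all(t == 0)) return(vol)
  d <- dim(vol@voxels)
  g <- .indexGrid(d)
  zi <- g$z - t[1] / vol@spacing[1]
  yi <- g$y - t[2] / vol@spacing[2]
  xi <- g$x - t[3] / vol@spacing[3]
  v <- .trilinear(vol@voxels, zi, yi, xi, fill = -1000,
                  method = interpolation)
  CTVolume(array(v, d), vol@spacing, vol@origin, vol@phase)
}

# Mutual information (nats) of two equal-length HU sample vectors over a
# bins x bins joint histogram; HU clamped to `window`.
.miHU <- function(a, b, bins, window = c(-1024, 200)) {
  cl <- function(v) {
    v <- pmin(pmax(v, window[1]), window[2])
    pmin(1L + floor((v - window[1]) / diff(window) * bins), bins)
  }
  ai <- cl(a); bi <- cl(b)
  joint <- tabulate(ai + bins * (bi - 1L), bins * bins) / length(ai)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

#' Refine a translation by maximizing mutual information
#'
#' Derivative-free (Nelder-Mead) local search over the 3-D translation,
#' scoring a 32-bin joint-histogram mutual information of the fixed volume
#' against the translated moving volume, restricted to \code{mask} (dilated)
#' when given, with HU clamped to [-1024, 200]. The returned shift never
#' scores below the initialization: if the optimizer fails to improve (or
#' the images are textureless), the initial shift is returned with
#' \code{usedInit = TRUE} and a warning.
#'
#' @param fixed,moving \linkS4class{CTVolume}s on the same grid.
#' @param init numeric(3) initial shift in mm (e.g. from
#'   \code{\link{centroidTranslation}}).
#' @param bins joint-histogram bins per axis, default 32.
#' @param mask optional \linkS4class{LungMask} restricting the metric region.
#' @param maxSamples cap on metric sample count (subsampled evenly).
#' @return list with \code{shift} (numeric(3) mm), \code{mi}, \code{miInit},
#'   and \code{usedInit}.
#' @export
refineTranslationMi <- function(fixed, moving, init = c(0, 0, 0), bins = 32,
                                mask = NULL, maxSamples = 40000) {
  stopifnot(identical(dim(fixed@voxels), dim(moving@voxels)))
  d <- dim(fixed@voxels)
  if (is.null(mask)) {
    sel <- seq_len(prod(d))
  } else {
    r2 <- 3^2 + 1e-9
    dil <- cpp_edt_sq(as.logical(mask@mask), as.integer(d)) <= r2
    sel <- which(dil)
  }
  if (length(sel) > maxSamples)
    sel <- sel[seq(1L, length(sel), length.out = maxSamples)]
  g <- .indexGrid(d)
  sz <- g$z[sel]; sy <- g$y[sel]; sx <- g$x[sel]
  fv <- fixed@voxels[sel]
  sampleMoving <- function(t) {
    .trilinear(moving@voxels, sz - t[1] / fixed@spacing[1],
               sy - t[2] / fixed@spacing[2], sx - t[3] / fixed@spacing[3],
               fill = -1000)
  }
  textureless <- sd(fv) < 1e-9 || sd(moving@voxels) < 1e-9
  miInit <- .miHU(fv, sampleMoving(init), bins)
  if (textureless) {
    .warnf("textureless volumes: mutual information is degenerate, keeping init")
    return(list(shift = init, mi = miInit, miInit = miInit, usedInit = TRUE))
  }
  score <- function(t) .miHU(fv, sampleMoving(t), bins)
  opt <- tryCatch(
    optim(init, function(t) -score(t), method = "Nelder-Mead",
          control = list(maxit = 150, reltol = 1e-7,
                         parscale = pmax(fixed@spacing, 1))),
    error = function(e) NULL)
  best <- if (!is.null(opt) && all(is.finite(opt$par)) &&
              -opt$value >= miInit)
    list(par = unname(opt$par), mi = -opt$value)
  else list(par = init, mi = miInit)
  # the subsampled MI surface is locally bumpy; polish with deterministic
  # per-axis line sweeps so the simplex cannot stall on a local ripple
  for (sweep in 1:2) {
    for (ax in 1:3) {
      offs <- seq(-2, 2, by = 0.25)
      cand <- vapply(offs, function(o) {
        t <- best$par; t[ax] <- t[ax] + o; score(t)
      }, numeric(1))
      k <- which.max(cand)
      if (cand[k] > best$mi) {
        best$par[ax] <- best$par[ax] + offs[k]
        best$mi <- cand[k]
      }
    }
  }
  if (best$mi < miInit) {
    .warnf("MI refinement failed to improve on the initialization")
    return(list(shift = init, mi = miInit, miInit = miInit, usedInit = TRUE))
  }
  list(shift = best$par, mi = best$mi, miInit = miInit, usedInit = FALSE)
}

#' Target registration error at paired landmarks
#'
#' Euclidean distance (mm) between corresponding landmarks of two sets;
#' the quality gate passes only when the maximum error is below
#' \code{thresholdMm}. Cases failing the gate are meant to be excluded from
#' analysis, not silently retained.
#'
#' @param fixedPts,movedPts data.frames with columns \code{id}, \code{z},
#'   \code{y}, \code{x} (mm); identical id sets.
#' @param thresholdMm acceptance threshold, default 2 mm.
#' @return a \code{TREReport} list: \code{perLandmarkError} (named mm),
#'   \code{meanError}, \code{maxError}, \code{pass}, \code{thresholdMm}.
#' @export
computeTre <- function(fixedPts, movedPts, thresholdMm = 2.0) {
  req <- c("id", "z", "y", "x")
  stopifnot(all(req %in% names(fixedPts)), all(req %in% names(movedPts)))
  if (!setequal(fixedPts$id, movedPts$id) ||
      anyDuplicated(fixedPts$id) || anyDuplicated(movedPts$id))
    .stopf("landmark id sets must match one-to-one")
  m <- movedPts[match(fixedPts$id, movedPts$id), ]
  err <- sqrt((fixedPts$z - m$z)^2 + (fixedPts$y - m$y)^2 +
                (fixedPts$x - m$x)^2)
  names(err) <- as.character(fixedPts$id)
  out <- list(perLandmarkError = err, meanError = mean(err),
              maxError = max(err), pass = max(err) < thresholdMm,
              thresholdMm = thresholdMm)
  class(out) <- "TREReport"
  out
}

#' @export
print.TREReport <- function(x, ...) {
  cat(sprintf("TRE over %d landmarks: mean %.3f mm, max %.3f mm -> %s (< %g mm)\n",
              length(x$perLandmarkError), x$meanError, x$maxError,
              if (x$pass) "PASS" else "FAIL", x$thresholdMm))
  invisible(x)
}
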