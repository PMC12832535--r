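# Gradient of a matrix along one axis: central differences in the interior,
# one-sided at the borders; h is the physical step (mm).
.grad2d <- function(mat, h, axis) {
  n <- dim(mat)[axis]
  out <- mat * 0
  if (axis == 1L) {
    out[2:(n - 1), ] <- (mat[3:n, ] - mat[1:(n - 2), ]) / (2 * h)
    out[1, ] <- (mat[2, ] - mat[1, ]) / h
    out[n, ] <- (mat[n, ] - mat[n - 1, ]) / h
  } else {
    out[, 2:(n - 1)] <- (mat[, 3:n] - mat[, 1:(n - 2)]) / (2 * h)
    out[, 1] <- (mat[, 2] - mat[, 1]) / h
    out[, n] <- (mat[, n] - mat[, n - 1]) / h
  }
  out
}

#' Gaussian regularization of a displacement field
#'
#' Separable Gaussian smoothing of both in-plane components, in voxel
#' units per axis \code{(z, y, x)}. Differentiating a dense optical-flow
#' field amplifies its voxel-scale matching noise, so the field is
#' regularized before strain computation; at the default scale the
#' attenuation of strain structure at wavelengths of tens of voxels is a
#' few percent, while voxel-scale noise is strongly suppressed. Set sigma
#' to zero to disable.
#'
#' @param disp a \linkS4class{DisplacementField}.
#' @param sigmaVox numeric(3), Gaussian sigma in voxels per axis
#'   \code{(z, y, x)}; default \code{c(1, 2, 2)}.
#' @return the smoothed \linkS4class{DisplacementField}.
#' @export
smoothDisplacementField <- function(disp, sigmaVox = c(1, 2, 2)) {
  stopifnot(is(disp, "DisplacementField"), length(sigmaVox) == 3)
  if (all(sigmaVox <= 0)) return(disp)
  sm <- function(a) {
    for (ax in 1:3)
      if (sigmaVox[ax] > 0)
        a <- .corAxis3d(a, .gaussKernel(sigmaVox[ax]), ax)
    a
  }
  new("DisplacementField", uy = sm(disp@uy), ux = sm(disp@ux),
      spacing = disp@spacing, dt = disp@dt)
}

#' In-plane strain tensors from a displacement field
#'
#' Infinitesimal strain: \code{eps_ij = (d u_i / d x_j + d u_j / d x_i) / 2},
#' with spatial derivatives taken per axial slice by central differences in
#' physical (mm) coordinates (one-sided at slice borders). The off-diagonal
#' component is stored once, so symmetry is exact by construction. Central
#' differences are exact on affine displacement fields.
#'
#' @param disp a \linkS4class{DisplacementField}.
#' @return a \linkS4class{StrainTensorField} (dimensionless).
#' @export
strainTensors <- function(disp) {
  stopifnot(is(disp, "DisplacementField"))
  d <- dim(disp@uy)
  hy <- disp@spacing[2]; hx <- disp@spacing[3]
  eyy <- array(0, d); exx <- array(0, d); eyx <- array(0, d)
  for (z in seq_len(d[1])) {
    uy <- disp@uy[z, , ]; ux <- disp@ux[z, , ]
    duy_dy <- .grad2d(uy, hy, 1L); duy_dx <- .grad2d(uy, hx, 2L)
    dux_dy <- .grad2d(ux, hy, 1L); dux_dx <- .grad2d(ux, hx, 2L)
    eyy[z, , ] <- duy_dy
    exx[z, , ] <- dux_dx
    eyx[z, , ] <- (duy_dx + dux_dy) / 2
  }
  new("StrainTensorField", eyy = eyy, eyx = eyx, exx = exx,
      spacing = disp@spacing)
}

#' Principal strains of a symmetric 2x2 tensor field
#'
#' Closed-form eigenvalues of each per-voxel tensor:
#' \code{mean +/- sqrt(((eyy - exx)/2)^2 + eyx^2)} with
#' \code{mean = (eyy + exx)/2}; \code{lambda1 >= lambda2} voxelwise, and the
#' result is invariant under rotation of the in-plane frame.
#'
#' @param tens a \linkS4class{StrainTensorField}.
#' @return list with 3-D arrays \code{l1} and \code{l2} (dimensionless).
#' @export
principalStrains <- function(tens) {
  stopifnot(is(tens, "StrainTensorField"))
  m <- (tens@eyy + tens@exx) / 2
  r <- sqrt(((tens@eyy - tens@exx) / 2)^2 + tens@eyx^2)
  list(l1 = m + r, l2 = m - r)
}

#' Per-patient strain summary (PSmax, PSmean, Speedmax)
#'
#' Over the masked voxels: the dimensionless PSmax/PSmean are the maximum
#' and mean of the first principal strain \code{lambda1}; Speedmax is the
#' maximum in-plane displacement magnitude divided by \code{dt} (mm/s).
#' In \code{"paper_mm"} mode the eigenvalue statistics are additionally
#' scaled by the mean in-plane voxel spacing to give mm-denominated values
#' comparable with clinical reports; the dimensionless values are always
#' co-reported. Maxima are true maxima by default; set
#' \code{robustPercentile} (e.g. 99.9) to guard against single-voxel flow
#' outliers.
#'
#' @param eigs eigenvalue grids from \code{\link{principalStrains}}.
#' @param disp the \linkS4class{DisplacementField} the tensors came from.
#' @param mask a nonempty \linkS4class{LungMask} on the same grid.
#' @param scaleMode \code{"paper_mm"} (default) or \code{"dimensionless"}.
#' @param robustPercentile optional percentile (0-100) replacing the maxima.
#' @param baselineShift optional numeric(2) in-plane rigid displacement
#'   (mm, \code{(y, x)}) added to the flow before the speed statistic --
#'   used by the pipeline to restore the registration translation, which
#'   carries no strain but does carry motion.
#' @return a \linkS4class{StrainSummary}.
#' @export
strainSummary <- function(eigs, disp, mask,
                          scaleMode = c("paper_mm", "dimensionless"),
                          robustPercentile = NULL,
                          baselineShift = c(0, 0)) {
  scaleMode <- match.arg(scaleMode)
  sel <- mask@mask > 0
  if (!any(sel)) .stopf("empty mask: no voxels to summarize")
  l1 <- eigs$l1[sel]
  speed <- sqrt((disp@uy[sel] + baselineShift[1])^2 +
                  (disp@ux[sel] + baselineShift[2])^2) / disp@dt
  pk <- function(v) {
    if (is.null(robustPercentile)) max(v)
    else as.numeric(quantile(v, robustPercentile / 100, names = FALSE))
  }
  dmax <- pk(l1); dmean <- mean(l1)
  scale <- if (scaleMode == "paper_mm") mean(disp@spacing[2:3]) else 1
  new("StrainSummary",
      PSmax = dmax * scale, PSmean = dmean * scale,
      Speedmax = pk(speed),
      dimensionlessPSmax = dmax, dimensionlessPSmean = dmean,
      nVoxelsAnalyzed = sum(sel))
}
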