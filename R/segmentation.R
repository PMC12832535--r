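#' Threshold a CT volume for air-like attenuation
#'
#' First step of lung segmentation: the mask is 1 exactly where
#' \code{HU <= thresholdHu}. At -400 HU this captures lung parenchyma
#' together with the exterior air, which the component filter removes next.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param thresholdHu scalar threshold, default -400.
#' @return a \linkS4class{LungMask} (possibly empty at this stage).
#' @export
thresholdLungs <- function(vol, thresholdHu = -400) {
  stopifnot(is(vol, "CTVolume"))
  LungMask((vol@voxels <= thresholdHu) * 1, vol@spacing, vol@origin)
}

#' Filter connected components by size and boundary contact
#'
#' Labels foreground components with 26-connectivity, then removes
#' components smaller than \code{minSizeVoxels} and (when
#' \code{excludeBoundary}) components touching the grid boundary -- this is
#' what discards the exterior-air component and small noise/artifact
#' regions in one pass.
#'
#' @param mask a \linkS4class{LungMask}.
#' @param minSizeVoxels minimum component size kept, default 1000.
#' @param excludeBoundary drop components touching the grid boundary.
#' @return the filtered \linkS4class{LungMask}.
#' @export
filterComponents <- function(mask, minSizeVoxels = 1000,
                             excludeBoundary = TRUE) {
  stopifnot(is(mask, "LungMask"))
  d <- dim(mask@mask)
  lab <- array(cpp_label3d(as.logical(mask@mask), as.integer(d), 26L), d)
  if (max(lab) == 0L) .stopf("empty segmentation: no foreground components")
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= minSizeVoxels
  if (excludeBoundary) {
    onB <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                    lab[, , c(1, d[3])]))
    keep[onB[onB > 0L]] <- FALSE
  }
  if (!any(keep)) .stopf("empty segmentation: all components filtered out")
  out <- array(0, d)
  out[lab > 0L & keep[pmax(lab, 1L)]] <- 1
  LungMask(out, mask@spacing, mask@origin)
}

#' Count connected components of a mask
#'
#' @param mask a \linkS4class{LungMask}.
#' @param connectivity 26 (default) or 6.
#' @return integer component count.
#' @export
countComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask@mask)
  max(cpp_label3d(as.logical(mask@mask), as.integer(d),
                  as.integer(connectivity)))
}

#' Morphological closing with a ball structuring element
#'
#' Dilation then erosion with a Euclidean ball of the given radius in voxel
#' units, computed through the exact squared distance transform (so the ball
#' is a true sphere, not a cube). Closing never removes voxels.
#'
#' @param mask a \linkS4class{LungMask}.
#' @param radiusVoxels ball radius in voxels, default 5.
#' @return the closed \linkS4class{LungMask}.
#' @export
closeMask <- function(mask, radiusVoxels = 5) {
  stopifnot(is(mask, "LungMask"))
  d <- dim(mask@mask)
  if (sum(mask@mask) == 0) return(mask)
  r2 <- radiusVoxels^2 + 1e-9
  dil <- array(cpp_edt_sq(as.logical(mask@mask), as.integer(d)) <= r2, d)
  ero <- array(cpp_edt_sq(!dil, as.integer(d)) > r2, d)
  out <- (ero | (mask@mask > 0)) * 1  # guard: closing is extensive
  LungMask(out, mask@spacing, mask@origin)
}

#' Fill interior holes of a binary mask
#'
#' Background voxels not reachable from the grid boundary via
#' 6-connectivity are set to foreground (the standard n-D binary hole fill,
#' with 6-connected background against 26-connected foreground).
#'
#' @param mask a \linkS4class{LungMask}.
#' @return the hole-filled \linkS4class{LungMask}.
#' @export
fillHoles <- function(mask) {
  stopifnot(is(mask, "LungMask"))
  d <- dim(mask@mask)
  reach <- array(cpp_background_from_boundary(as.logical(mask@mask),
                                              as.integer(d)), d)
  LungMask((mask@mask > 0 | !reach) * 1, mask@spacing, mask@origin)
}

#' Segment the lungs from a CT volume
#'
#' The four-step adaptive-threshold workflow: threshold at
#' \code{thresholdHu}, 26-connectivity component filtering (size >=
#' \code{minSizeVoxels}, boundary components removed), ball closing of
#' radius \code{closeRadiusVoxels}, then n-D hole filling. Tumour voxels are
#' not excluded: small lesions are left inside the mask so the whole
#' parenchyma contributes to strain statistics. An optional lesion mask can
#' subtract them.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param thresholdHu threshold, default -400 HU.
#' @param minSizeVoxels component size floor, default 1000.
#' @param closeRadiusVoxels closing ball radius, default 5.
#' @param lesionMask optional \linkS4class{LungMask} of lesion voxels to
#'   exclude from the final mask (default \code{NULL}: include them).
#' @return a \linkS4class{LungMask}.
#' @export
segmentLungs <- function(vol, thresholdHu = -400, minSizeVoxels = 1000,
                         closeRadiusVoxels = 5, lesionMask = NULL) {
  m <- thresholdLungs(vol, thresholdHu)
  m <- filterComponents(m, minSizeVoxels, excludeBoundary = TRUE)
  m <- closeMask(m, closeRadiusVoxels)
  m <- fillHoles(m)
  if (!is.null(lesionMask)) {
    m@mask <- (m@mask > 0 & !(lesionMask@mask > 0)) * 1
    if (sum(m@mask) == 0) .stopf("empty segmentation after lesion exclusion")
  }
  m
}

#' Mask volume in millilitres
#'
#' @param mask a \linkS4class{LungMask}.
#' @return voxel count times voxel volume (mm^3) / 1000.
#' @export
maskVolumeMl <- function(mask) {
  stopifnot(is(mask, "LungMask"))
  sum(mask@mask) * prod(mask@spacing) / 1000
}

#' Dice overlap between two masks
#'
#' @param a,b \linkS4class{LungMask} objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a@mask), dim(b@mask)))
  2 * sum(a@mask > 0 & b@mask > 0) / (sum(a@mask) + sum(b@mask))
}
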