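#' Accessors for imaging containers
#'
#' \code{voxels} returns the raw 3-D array (HU for volumes, 0/1 for masks);
#' \code{voxelSpacing} and \code{voxelOrigin} return the mm geometry in
#' \code{(z, y, x)} order; \code{phaseLabel} returns the respiratory-phase
#' tag of a volume.
#'
#' @param x a \linkS4class{CTVolume}, \linkS4class{LungMask},
#'   \linkS4class{DisplacementField} or \linkS4class{StrainTensorField}.
#' @return \code{voxels}: a 3-D array; \code{voxelSpacing},
#'   \code{voxelOrigin}: numeric(3); \code{phaseLabel}: character(1).
#' @aliases voxels voxelSpacing voxelOrigin phaseLabel
#' @name accessors
#' @examples
#' v <- CTVolume(array(-800, c(4, 4, 4)), spacing = c(2.5, 1.5, 1.5))
#' voxelSpacing(v)
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("phaseLabel", function(x) standardGeneric("phaseLabel"))

#' @rdname accessors
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname accessors
setMethod("voxels", "LungMask", function(x) x@mask)
#' @rdname accessors
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LungMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "StrainTensorField", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelOrigin", "CTVolume", function(x) x@origin)
#' @rdname accessors
setMethod("voxelOrigin", "LungMask", function(x) x@origin)
#' @rdname accessors
setMethod("phaseLabel", "CTVolume", function(x) x@phase)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g mm",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  if (!is.na(object@phase)) cat(sprintf(", phase %s", object@phase))
  cat(sprintf("\n  HU range [%.0f, %.0f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LungMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("LungMask %d x %d x %d, %d voxels set (%.2f mL)\n",
              d[1], d[2], d[3], sum(object@mask),
              sum(object@mask) * prod(object@spacing) / 1000))
})

setMethod("show", "DisplacementField", function(object) {
  m <- sqrt(object@uy^2 + object@ux^2)
  cat(sprintf(
    "DisplacementField %s, dt %.3g s, |u| median %.3g mm, max %.3g mm\n",
    paste(dim(object@uy), collapse = " x "), object@dt,
    stats::median(m), max(m)))
})

setMethod("show", "StrainTensorField", function(object) {
  cat(sprintf("StrainTensorField %s (dimensionless)\n",
              paste(dim(object@eyy), collapse = " x ")))
})

setMethod("show", "StrainSummary", function(object) {
  cat(sprintf(
    paste0("StrainSummary: PSmax %.3f mm, PSmean %.3f mm, ",
           "Speedmax %.2f mm/s\n  (dimensionless PSmax %.4f, ",
           "PSmean %.4f; %d voxels)\n"),
    object@PSmax, object@PSmean, object@Speedmax,
    object@dimensionlessPSmax, object@dimensionlessPSmean,
    object@nVoxelsAnalyzed))
})

#' Construct a CTVolume
#'
#' @param voxels 3-D numeric array of HU, dim \code{(nz, ny, nx)}.
#' @param spacing numeric(3) mm in \code{(z, y, x)} order.
#' @param origin numeric(3) mm; default zero.
#' @param phase optional phase label.
#' @return a validated \linkS4class{CTVolume}.
#' @export
#' @examples
#' CTVolume(array(-800, c(8, 8, 8)), spacing = c(2.5, 1.5, 1.5))
CTVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                     phase = NA_character_) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), phase = as.character(phase))
}

#' Construct a LungMask
#'
#' @param mask 3-D array of 0/1 (logical accepted).
#' @param spacing numeric(3) mm in \code{(z, y, x)} order.
#' @param origin numeric(3) mm.
#' @return a validated \linkS4class{LungMask}.
#' @export
LungMask <- function(mask, spacing, origin = c(0, 0, 0)) {
  storage.mode(mask) <- "double"
  new("LungMask", mask = mask, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a PhaseSeries
#'
#' @param volumes list of \linkS4class{CTVolume}, one per respiratory phase.
#' @param phaseFractions numeric, cycle fractions in [0, 1), strictly
#'   increasing (e.g. \code{seq(0, 0.9, by = 0.1)}).
#' @return a validated \linkS4class{PhaseSeries}.
#' @export
PhaseSeries <- function(volumes, phaseFractions) {
  new("PhaseSeries", volumes = volumes,
      phaseFractions = as.numeric(phaseFractions))
}
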