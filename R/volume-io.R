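#' Read a CT volume from NIfTI or a DICOM series
#'
#' Volumes are returned in the package's fixed geometry convention:
#' axis order \code{(slice z, row y, column x)}, 0-based voxel indices,
#' physical position \code{origin + index * spacing} in mm. The direction
#' matrix must be axis-aligned with positive diagonal; oblique acquisitions
#' are rejected. For DICOM, the rescale slope/intercept is applied so that
#' voxel values are Hounsfield units.
#'
#' @param path a \code{.nii}/\code{.nii.gz} file, or a directory containing
#'   one DICOM series.
#' @param format \code{"nifti"} or \code{"dicom_series"}.
#' @param phase optional respiratory-phase label to attach.
#' @return a \linkS4class{CTVolume}.
#' @seealso \code{\link{saveVolume}}, \code{\link{readDicomSeries}}
#' @export
loadVolume <- function(path, format = c("nifti", "dicom_series"),
                       phase = NA_character_) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) .stopf("unreadable NIfTI: %s",
                                               conditionMessage(e)))
    aff <- RNifti::xform(img)
    rot <- aff[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))) ||
        any(diag(rot) <= 0))
      .stopf("oblique or flipped acquisition geometry is not supported")
    arr <- aperm(as.array(img), c(3, 2, 1))
    CTVolume(arr, spacing = rev(diag(rot)), origin = rev(aff[1:3, 4]),
             phase = phase)
  } else {
    readDicomSeries(path, phase = phase)
  }
}

#' Write a CT volume (or mask) as NIfTI
#'
#' Voxels, spacing and origin round-trip exactly through
#' \code{\link{loadVolume}} (data are written as float64).
#'
#' @param vol a \linkS4class{CTVolume} or \linkS4class{LungMask}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return the path, invisibly.
#' @export
saveVolume <- function(vol, path) {
  if (is(vol, "LungMask"))
    vol <- CTVolume(vol@mask, vol@spacing, vol@origin)
  stopifnot(is(vol, "CTVolume"))
  validObject(vol)
  arr <- aperm(vol@voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  sxyz <- rev(vol@spacing)
  RNifti::pixdim(img) <- sxyz
  aff <- diag(c(sxyz, 1))
  aff[1:3, 4] <- rev(vol@origin)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = "double"); TRUE},
                 error = function(e) FALSE)
  if (!ok) .stopf("cannot write NIfTI to %s", path)
  invisible(path)
}

#' Read a 0/1 mask stored as NIfTI
#'
#' @param path NIfTI file written by \code{\link{saveVolume}} (or any file
#'   whose voxels are 0/1 up to rounding).
#' @return a \linkS4class{LungMask}.
#' @export
loadMask <- function(path) {
  v <- loadVolume(path, "nifti")
  LungMask((v@voxels > 0.5) * 1, v@spacing, v@origin)
}

#' Resample a CT volume by a scale factor
#'
#' The output grid has \code{round(shape * factor)} voxels per axis and
#' spacing \code{spacing / factor}; voxel-centre grids are centre-aligned so
#' the physical extent is preserved to within one output voxel. Use
#' \code{"nearest"} for label/mask grids.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param factor scale in (0, 4]; e.g. 0.5 halves the resolution.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return a resampled \linkS4class{CTVolume}.
#' @export
resampleVolume <- function(vol, factor,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(vol, "CTVolume"))
  if (!is.finite(factor) || factor <= 0 || factor > 4)
    .stopf("factor must be in (0, 4]")
  d <- dim(vol@voxels)
  dout <- as.integer(round(d * factor))
  if (any(dout < 2L))
    .stopf("resampling factor %.3g collapses an axis below 2 voxels", factor)
  if (identical(dout, d) && abs(factor - 1) < 1e-12) return(vol)
  spout <- vol@spacing / factor
  centre <- vol@origin + (d - 1) / 2 * vol@spacing
  oout <- centre - (dout - 1) / 2 * spout
  g <- .indexGrid(dout)
  # physical position of each output voxel, converted to input index space
  zi <- (oout[1] + (g$z - 1) * spout[1] - vol@origin[1]) / vol@spacing[1] + 1
  yi <- (oout[2] + (g$y - 1) * spout[2] - vol@origin[2]) / vol@spacing[2] + 1
  xi <- (oout[3] + (g$x - 1) * spout[3] - vol@origin[3]) / vol@spacing[3] + 1
  v <- .trilinear(vol@voxels, zi, yi, xi, fill = NA, method = interpolation)
  # output centres lie inside the input extent; clamp handled out-of-range
  v[is.na(v)] <- -1000
  CTVolume(array(v, dout), spout, oout, vol@phase)
}

#' Select end-inspiration and end-expiration phases by lung volume
#'
#' EI is the phase whose mask encloses the largest volume (mL), EE the
#' smallest; ties are broken toward the earlier phase fraction (with a
#' warning). Phase labels in the input are deliberately ignored: vendor 0%
#' conventions are inconsistent, so the extremes are always measured.
#'
#' @param series a \linkS4class{PhaseSeries}.
#' @param masks list of \linkS4class{LungMask}, one per phase,
#'   geometry-aligned with the series.
#' @return list with elements \code{EI} and \code{EE} (\code{CTVolume}s with
#'   phase labels set), plus \code{volumesMl} and the selected indices.
#' @export
selectExtremePhases <- function(series, masks) {
  stopifnot(is(series, "PhaseSeries"))
  n <- length(series@volumes)
  if (n < 2L) .stopf("need at least 2 phases, got %d", n)
  if (length(masks) != n) .stopf("need one mask per phase")
  vols <- vapply(masks, maskVolumeMl, numeric(1))
  iEI <- which(vols == max(vols))[1]   # earliest fraction wins ties
  iEE <- which(vols == min(vols))[1]
  if (sum(vols == max(vols)) > 1 || sum(vols == min(vols)) > 1)
    .warnf("tied lung volumes; ties broken toward the earlier phase")
  ei <- series@volumes[[iEI]]; ei@phase <- "EI"
  ee <- series@volumes[[iEE]]; ee@phase <- "EE"
  list(EI = ei, EE = ee, volumesMl = vols, indexEI = iEI, indexEE = iEE)
}
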