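#' @import methods
#' @importFrom stats coef cor fisher.test glm optim pnorm pt qnorm qt
#'   quantile rnorm runif sd setNames shapiro.test t.test chisq.test
#'   wilcox.test binomial var uniroot rbinom fitted predict median dnorm
#'   complete.cases
#' @importFrom utils head tail
#' @useDynLib lungstrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CTVolume: a 3-D CT grid in Hounsfield units
#'
#' The basic imaging container. Voxels are stored as a 3-D array in
#' \code{(slice z, row y, column x)} order; \code{spacing} and \code{origin}
#' use the same axis order, in millimetres. The physical position of voxel
#' index \code{(i, j, k)} (0-based) is \code{origin + c(i, j, k) * spacing};
#' the direction matrix is assumed identity, and oblique acquisitions are
#' rejected at load time.
#'
#' @slot voxels 3-D numeric array of HU values, dim \code{(nz, ny, nx)}.
#' @slot spacing numeric(3), voxel size in mm, \code{(z, y, x)} order.
#' @slot origin numeric(3), physical position of voxel (0,0,0) in mm.
#' @slot phase character(1), optional respiratory-phase label (e.g.
#'   \code{"EI"}, \code{"EE"}, \code{"0%"}); \code{NA} when unknown.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 phase = "character"),
  prototype(phase = NA_character_)
)

setValidity("CTVolume", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 3L) msg <- c(msg, "voxels must be a 3-D array")
  else if (any(d < 2L)) msg <- c(msg, "grid needs >= 2 voxels per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (z, y, x)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (z, y, x)")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "HU values must all be finite")
  if (length(msg)) msg else TRUE
})

#' LungMask: a binary mask aligned to a CTVolume
#'
#' @slot mask 3-D array with values 0/1, same shape as its source volume.
#' @slot spacing numeric(3), inherited mm spacing, \code{(z, y, x)} order.
#' @slot origin numeric(3), inherited origin in mm.
#' @export
setClass("LungMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric")
)

setValidity("LungMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L) msg <- c(msg, "mask must be 3-D")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask values must be 0 or 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' PhaseSeries: an ordered set of respiratory-phase volumes
#'
#' @slot volumes list of \linkS4class{CTVolume}, one per phase, sharing grid
#'   shape and spacing.
#' @slot phaseFractions numeric, matching cycle fractions in [0, 1),
#'   strictly increasing.
#' @export
setClass("PhaseSeries",
  representation(volumes = "list", phaseFractions = "numeric")
)

setValidity("PhaseSeries", function(object) {
  msg <- character()
  if (length(object@volumes) != length(object@phaseFractions))
    msg <- c(msg, "volumes and phaseFractions must have equal length")
  if (length(object@phaseFractions) &&
      (any(object@phaseFractions < 0) || any(object@phaseFractions >= 1) ||
       any(diff(object@phaseFractions) <= 0)))
    msg <- c(msg, "phase fractions must be strictly increasing within [0, 1)")
  if (length(object@volumes)) {
    if (!all(vapply(object@volumes, is, logical(1), "CTVolume")))
      msg <- c(msg, "all elements must be CTVolume objects")
    else {
      d1 <- dim(object@volumes[[1]]@voxels)
      s1 <- object@volumes[[1]]@spacing
      same <- vapply(object@volumes, function(v)
        identical(dim(v@voxels), d1) && isTRUE(all.equal(v@spacing, s1)),
        logical(1))
      if (!all(same)) msg <- c(msg, "volumes must share shape and spacing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DisplacementField: dense in-plane motion vectors
#'
#' Per-voxel in-plane displacement in millimetres, computed slice-wise on
#' axial planes. \code{uy}/\code{ux} have the shape of the source volume;
#' \code{dt} is the time between the two phases in seconds.
#'
#' @slot uy 3-D array, row-direction (y) displacement, mm.
#' @slot ux 3-D array, column-direction (x) displacement, mm.
#' @slot spacing numeric(3) mm, \code{(z, y, x)}.
#' @slot dt numeric(1), inter-phase interval in seconds, > 0.
#' @export
setClass("DisplacementField",
  representation(uy = "array", ux = "array", spacing = "numeric",
                 dt = "numeric")
)

setValidity("DisplacementField", function(object) {
  msg <- character()
  if (!identical(dim(object@uy), dim(object@ux)))
    msg <- c(msg, "uy and ux must have identical shape")
  if (any(!is.finite(object@uy)) || any(!is.finite(object@ux)))
    msg <- c(msg, "displacement components must be finite")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' StrainTensorField: per-voxel symmetric 2x2 in-plane strain
#'
#' Infinitesimal strain, the symmetric part of the displacement gradient
#' with derivatives taken in physical (mm) coordinates; dimensionless.
#' Symmetry is exact by construction (a single off-diagonal slot).
#'
#' @slot eyy 3-D array, normal strain along y.
#' @slot eyx 3-D array, shear component (= exy).
#' @slot exx 3-D array, normal strain along x.
#' @slot spacing numeric(3) mm.
#' @export
setClass("StrainTensorField",
  representation(eyy = "array", eyx = "array", exx = "array",
                 spacing = "numeric")
)

setValidity("StrainTensorField", function(object) {
  msg <- character()
  if (!identical(dim(object@eyy), dim(object@exx)) ||
      !identical(dim(object@eyy), dim(object@eyx)))
    msg <- c(msg, "tensor component grids must share shape")
  if (any(!is.finite(object@eyy)) || any(!is.finite(object@eyx)) ||
      any(!is.finite(object@exx)))
    msg <- c(msg, "tensor components must be finite")
  if (length(msg)) msg else TRUE
})

#' StrainSummary: per-patient strain biomarkers
#'
#' PSmax and PSmean are statistics of the first principal strain (largest
#' eigenvalue of the symmetric strain tensor) over the lung mask; Speedmax is
#' the maximum displacement magnitude divided by the inter-phase interval.
#' The dimensionless eigenvalue statistics are always carried alongside the
#' mm-scaled values (see \code{\link{strainSummary}} for the scaling rule).
#'
#' @slot PSmax numeric(1), mm-scaled maximum principal strain.
#' @slot PSmean numeric(1), mm-scaled mean principal strain.
#' @slot Speedmax numeric(1), mm/s.
#' @slot dimensionlessPSmax numeric(1), max of the eigenvalue field.
#' @slot dimensionlessPSmean numeric(1), mean of the eigenvalue field.
#' @slot nVoxelsAnalyzed integer(1), masked voxel count.
#' @export
setClass("StrainSummary",
  representation(PSmax = "numeric", PSmean = "numeric", Speedmax = "numeric",
                 dimensionlessPSmax = "numeric",
                 dimensionlessPSmean = "numeric",
                 nVoxelsAnalyzed = "integer")
)

setValidity("StrainSummary", function(object) {
  msg <- character()
  if (object@Speedmax < 0) msg <- c(msg, "Speedmax must be >= 0")
  if (object@nVoxelsAnalyzed <= 0L)
    msg <- c(msg, "nVoxelsAnalyzed must be positive")
  if (object@dimensionlessPSmax < object@dimensionlessPSmean - 1e-12)
    msg <- c(msg, "PSmax must be >= PSmean on the same mask")
  if (length(msg)) msg else TRUE
})
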