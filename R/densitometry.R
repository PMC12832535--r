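#' Low attenuation area percentage (LAA\%)
#'
#' Percentage of masked voxels at or below the emphysema threshold
#' (default -950 HU).
#'
#' @param vol a \linkS4class{CTVolume} (end-inspiration by convention).
#' @param mask a nonempty \linkS4class{LungMask}.
#' @param thresholdHu threshold, default -950.
#' @return percentage in [0, 100].
#' @export
laaPercent <- function(vol, mask, thresholdHu = -950) {
  hu <- .maskedHu(vol, mask)
  100 * mean(hu <= thresholdHu)
}

#' Mean lung density (MLD)
#'
#' @inheritParams laaPercent
#' @return arithmetic mean of masked HU.
#' @export
meanLungDensity <- function(vol, mask) mean(.maskedHu(vol, mask))

#' Percentile of the lung attenuation histogram
#'
#' The q-th percentile of masked HU with linear interpolation between
#' closest order statistics (R's type-7 quantile; at small n the
#' interpolation rule matters, so it is fixed and documented here). The
#' 15th percentile is the Perc15 emphysema index: the prose "pixel index"
#' reading as a percentage is dimensionally inconsistent with HU-valued
#' reports, so the percentile convention is the labeled output, while the
#' percentage-below-threshold variant remains available as
#' \code{\link{laaPercent}}.
#'
#' @inheritParams laaPercent
#' @param q percentile in (0, 100), default 15.
#' @return HU value, bounded by the masked min/max.
#' @export
percentileDensity <- function(vol, mask, q = 15) {
  if (q <= 0 || q >= 100) .stopf("q must be in (0, 100)")
  as.numeric(quantile(.maskedHu(vol, mask), q / 100, type = 7,
                      names = FALSE))
}

.maskedHu <- function(vol, mask) {
  stopifnot(is(vol, "CTVolume"), is(mask, "LungMask"),
            identical(dim(vol@voxels), dim(mask@mask)))
  sel <- mask@mask > 0
  if (!any(sel)) .stopf("empty mask")
  vol@voxels[sel]
}

#' End-inspiration CT densitometry bundle
#'
#' LAA\%, mean lung density and the 15th-percentile density over the lung
#' mask, in one call.
#'
#' @inheritParams laaPercent
#' @param laaThresholdHu LAA threshold, default -950.
#' @param percentile Perc percentile, default 15.
#' @return a \code{DensitometryResult} list: \code{laaPercent},
#'   \code{mldHu}, \code{perc15Hu}, plus the parameters used.
#' @export
densitometry <- function(vol, mask, laaThresholdHu = -950, percentile = 15) {
  out <- list(laaPercent = laaPercent(vol, mask, laaThresholdHu),
              mldHu = meanLungDensity(vol, mask),
              perc15Hu = percentileDensity(vol, mask, percentile),
              laaThresholdHu = laaThresholdHu, percentile = percentile)
  class(out) <- "DensitometryResult"
  out
}

#' @export
print.DensitometryResult <- function(x, ...) {
  cat(sprintf("Densitometry: LAA%%(<= %g HU) = %.2f%%, MLD = %.2f HU, Perc%g = %.2f HU\n",
              x$laaThresholdHu, x$laaPercent, x$mldHu, x$percentile,
              x$perc15Hu))
  invisible(x)
}
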