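#' Specification of a deformable two-lung CT phantom
#'
#' The phantom is an analytic continuous scene -- two ellipsoidal lungs of
#' band-limited cosine-sum parenchymal texture threaded with vessel
#' spheres, inside a soft-tissue body cylinder surrounded by air -- sampled
#' exactly at voxel centres for end-inspiration and at the analytically
#' inverted deformation for end-expiration, so both phases carry identical
#' point-spread characteristics (no resampling blur asymmetry). The
#' deformation family is a bulk translation, a diaphragm-like axial
#' compression growing linearly toward the caudal pole, an in-plane
#' sinusoid (which carries the nonzero in-plane strain), and a small
#' uniform shear; it is smooth, closed-form differentiable and invertible
#' at the default amplitudes (the Jacobian is checked at generation time).
#'
#' Defaults: 64 x 128 x 128 grid at 2.5 x 1.5 x 1.5 mm (the analysis
#' resolution), parenchyma -850 +/- 40 HU, ~2\% vessel volume fraction,
#' 7.3\% planted emphysema voxels, bulk shift (2, 1, 2) mm, 4 mm axial
#' compression, in-plane sinusoid amplitudes (3, 4) mm at 120 mm
#' wavelength, 2 s phase interval.
#'
#' @param shape grid dim \code{(nz, ny, nx)}.
#' @param spacing voxel size mm \code{(z, y, x)}.
#' @param parenchymaHu,textureSd mean and SD of lung texture (HU). The
#'   texture passes through a smooth tanh compression at
#'   \code{+/- textureClip} so no parenchyma voxel reaches the -950 HU
#'   emphysema threshold and the planted fraction stays exact.
#' @param textureClip texture soft-clip half-range, HU.
#' @param textureSigmaVox texture correlation length, voxels.
#' @param vesselCount small vessel spheres per lung (texture features).
#' @param vesselHuRange HU range of the small vessels.
#' @param vesselRadiusRange radius range (mm) of the small vessels.
#' @param landmarkVesselHu,landmarkVesselRadiusMm the \code{nLandmarks}
#'   bright landmark vessels (bifurcation surrogates).
#' @param emphysemaFraction fraction of lung-mask voxels planted at
#'   <= -950 HU.
#' @param bulkTranslation mm \code{(z, y, x)}.
#' @param axialCompressionMm peak caudal axial displacement, mm.
#' @param inplaneAmplitude mm \code{(y, x)} sinusoid amplitudes.
#' @param wavelengthMm in-plane sinusoid wavelength, mm.
#' @param shear uniform du_x/dy shear (dimensionless).
#' @param noiseSd independent per-scan HU noise SD (clipped at 2 SD).
#' @param dt EI-to-EE interval, seconds.
#' @param nLandmarks generator-known landmarks, >= 8.
#' @param seed RNG seed.
#' @return a \code{PhantomSpec} list.
#' @export
phantomSpec <- function(shape = c(64, 128, 128), spacing = c(2.5, 1.5, 1.5),
                        parenchymaHu = -850, textureSd = 40,
                        textureClip = 88, textureSigmaVox = 1.5,
                        vesselCount = 150,
                        vesselHuRange = c(-450, -50),
                        vesselRadiusRange = c(1.5, 3.5),
                        landmarkVesselHu = 0, landmarkVesselRadiusMm = 3,
                        emphysemaFraction = 0.073,
                        bulkTranslation = c(2, 1, 2),
                        axialCompressionMm = 4,
                        inplaneAmplitude = c(3, 4), wavelengthMm = 120,
                        shear = 0.02, noiseSd = 5, dt = 2.0,
                        nLandmarks = 10, seed = 1) {
  extent <- shape * spacing
  spec <- list(shape = as.integer(shape), spacing = spacing,
               extent = extent,
               lungCentres = list(c(extent[1] / 2, extent[2] / 2,
                                    extent[3] * 0.29),
                                  c(extent[1] / 2, extent[2] / 2,
                                    extent[3] * 0.71)),
               lungSemiaxes = c(0.34 * extent[1], 0.29 * extent[2],
                                0.145 * extent[3]),
               bodySemiaxes = c(0.46 * extent[2], 0.48 * extent[3]),
               parenchymaHu = parenchymaHu, textureSd = textureSd,
               textureClip = textureClip,
               textureSigmaVox = textureSigmaVox,
               vesselCount = vesselCount,
               vesselHuRange = vesselHuRange,
               vesselRadiusRange = vesselRadiusRange,
               landmarkVesselHu = landmarkVesselHu,
               landmarkVesselRadiusMm = landmarkVesselRadiusMm,
               emphysemaFraction = emphysemaFraction,
               bulkTranslation = bulkTranslation,
               axialCompressionMm = axialCompressionMm,
               inplaneAmplitude = inplaneAmplitude,
               wavelengthMm = wavelengthMm, shear = shear,
               noiseSd = noiseSd, dt = dt,
               nLandmarks = as.integer(nLandmarks), seed = seed,
               sinPhase = c(extent[2] / 2, extent[3] * 0.29))
  class(spec) <- "PhantomSpec"
  spec
}

# displacement components at physical positions (mm); z,y,x vectors
.phantomU <- function(spec, z, y, x) {
  k <- 2 * pi / spec$wavelengthMm
  t <- spec$bulkTranslation
  list(uz = t[1] - spec$axialCompressionMm * z / spec$extent[1],
       uy = t[2] + spec$inplaneAmplitude[1] * sin(k * (y - spec$sinPhase[1])),
       ux = t[3] + spec$inplaneAmplitude[2] * sin(k * (x - spec$sinPhase[2])) +
         spec$shear * (y - spec$extent[2] / 2))
}

#' Analytic displacement of a phantom deformation
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param points matrix/data.frame of positions mm, columns \code{(z, y, x)}.
#' @return data.frame with \code{uz}, \code{uy}, \code{ux} (mm).
#' @export
analyticDisplacement <- function(spec, points) {
  points <- as.matrix(points)
  u <- .phantomU(spec, points[, 1], points[, 2], points[, 3])
  data.frame(uz = u$uz, uy = u$uy, ux = u$ux)
}

#' Analytic in-plane strain tensor of a phantom deformation
#'
#' Exact symbolic derivative of the generator's displacement: the symmetric
#' part of the in-plane gradient,
#' \code{eyy = Ay k cos(k (y - y0))}, \code{exx = Ax k cos(k (x - x0))},
#' \code{eyx = shear / 2}.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param point position mm \code{(z, y, x)}, inside the grid.
#' @return 2x2 symmetric matrix, rows/cols ordered (y, x).
#' @export
analyticStrain <- function(spec, point) {
  if (any(point < 0) || any(point > spec$extent))
    .stopf("point outside the phantom grid")
  k <- 2 * pi / spec$wavelengthMm
  eyy <- spec$inplaneAmplitude[1] * k * cos(k * (point[2] - spec$sinPhase[1]))
  exx <- spec$inplaneAmplitude[2] * k * cos(k * (point[3] - spec$sinPhase[2]))
  eyx <- spec$shear / 2
  matrix(c(eyy, eyx, eyx, exx), 2, 2)
}

.phantomStrainFields <- function(spec, ym, xm) {
  k <- 2 * pi / spec$wavelengthMm
  list(eyy = spec$inplaneAmplitude[1] * k * cos(k * (ym - spec$sinPhase[1])),
       exx = spec$inplaneAmplitude[2] * k * cos(k * (xm - spec$sinPhase[2])),
       eyx = array(spec$shear / 2, dim(ym)))
}

.insideEllipsoid <- function(zm, ym, xm, centre, semi) {
  ((zm - centre[1]) / semi[1])^2 + ((ym - centre[2]) / semi[2])^2 +
    ((xm - centre[3]) / semi[3])^2 <= 1
}

# Analytic scene model: geometry + texture + vessels, evaluated at any
# physical positions. `model` carries the sampled random components.
.phantomSceneModel <- function(spec) {
  K <- 120L
  sigc <- spec$textureSigmaVox * spec$spacing
  model <- list(
    kz = rnorm(K, 0, 1 / sigc[1]), ky = rnorm(K, 0, 1 / sigc[2]),
    kx = rnorm(K, 0, 1 / sigc[3]), phase = runif(K, 0, 2 * pi),
    amp = spec$textureSd * sqrt(2 / K))
  vessels <- list()
  for (li in 1:2) {
    cen <- spec$lungCentres[[li]]
    # landmark vessels first (bright, fixed size), then texture vessels
    nv <- 0L
    nWantLm <- ceiling(spec$nLandmarks / 2)
    while (nv < nWantLm + spec$vesselCount) {
      p <- cen + runif(3, -1, 1) * 0.85 * spec$lungSemiaxes
      if (sum(((p - cen) / (0.92 * spec$lungSemiaxes))^2) > 1) next
      # landmark vessels stay well inside (smaller axial spread at the gate)
      if (nv < nWantLm &&
          sum(((p - cen) / (0.72 * spec$lungSemiaxes))^2) > 1) next
      nv <- nv + 1L
      if (nv <= nWantLm)
        vessels[[length(vessels) + 1L]] <-
          c(p, spec$landmarkVesselRadiusMm, spec$landmarkVesselHu, 1)
      else
        vessels[[length(vessels) + 1L]] <-
          c(p, runif(1, spec$vesselRadiusRange[1], spec$vesselRadiusRange[2]),
            runif(1, spec$vesselHuRange[1], spec$vesselHuRange[2]), 0)
    }
  }
  model$vessels <- do.call(rbind, vessels)
  colnames(model$vessels) <- c("z", "y", "x", "r", "hu", "landmark")
  model
}

.phantomLungAt <- function(spec, z, y, x) {
  .insideEllipsoid(z, y, x, spec$lungCentres[[1]], spec$lungSemiaxes) |
    .insideEllipsoid(z, y, x, spec$lungCentres[[2]], spec$lungSemiaxes)
}

.phantomHuAt <- function(spec, model, z, y, x) {
  hu <- rep(-1000, length(z))
  body <- ((y - spec$extent[2] / 2) / spec$bodySemiaxes[1])^2 +
    ((x - spec$extent[3] / 2) / spec$bodySemiaxes[2])^2 <= 1
  hu[body] <- 30
  L <- .phantomLungAt(spec, z, y, x)
  zi <- z[L]; yi <- y[L]; xi <- x[L]
  tex <- 0
  for (i in seq_along(model$kz))
    tex <- tex + model$amp * cos(model$kz[i] * zi + model$ky[i] * yi +
                                   model$kx[i] * xi + model$phase[i])
  tex <- spec$textureClip * tanh(tex / spec$textureClip)
  hu[L] <- spec$parenchymaHu + tex
  idx <- which(L)
  V <- model$vessels
  for (v in seq_len(nrow(V))) {
    s <- which(abs(zi - V[v, 1]) <= V[v, 4] & abs(yi - V[v, 2]) <= V[v, 4] &
                 abs(xi - V[v, 3]) <= V[v, 4])
    if (length(s)) {
      r2 <- (zi[s] - V[v, 1])^2 + (yi[s] - V[v, 2])^2 + (xi[s] - V[v, 3])^2
      hu[idx[s[r2 <= V[v, 4]^2]]] <- V[v, 5]
    }
  }
  list(hu = hu, lung = L)
}

#' Generate a deformable lung phantom with known truth
#'
#' End-inspiration samples the analytic scene at voxel centres;
#' end-expiration samples it at the numerically inverted analytic
#' deformation (fixed-point inversion of \code{x + u(x)}), so the forward
#' displacement truth is exact at EI voxel centres and both phases share
#' identical sampling characteristics. Emphysema voxels are planted on the
#' EI grid with an exact count and mirrored into EE at their deformed
#' positions. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return a \code{PhantomTruth} list: \code{EI}, \code{EE}
#'   (\linkS4class{CTVolume}), \code{truthMask} (\linkS4class{LungMask}),
#'   \code{dispTrue} (\linkS4class{DisplacementField}, in-plane),
#'   \code{uzTrue} (array, mm), \code{strainTrue}
#'   (\linkS4class{StrainTensorField}), \code{landmarksEI},
#'   \code{landmarksEE} (data.frames id/z/y/x mm), \code{lungVolumeMl}
#'   (closed-form ellipsoid volume), \code{emphysemaPercentTrue},
#'   \code{spec}.
#' @export
makePhantom <- function(spec = phantomSpec()) {
  set.seed(spec$seed)
  d <- spec$shape; sp <- spec$spacing
  g <- .indexGrid(d)
  zm <- (g$z - 1) * sp[1]; ym <- (g$y - 1) * sp[2]; xm <- (g$x - 1) * sp[3]

  # invertibility: the analytic Jacobian of x + u(x) must stay positive
  k <- 2 * pi / spec$wavelengthMm
  jzz <- 1 - spec$axialCompressionMm / spec$extent[1]
  jyy <- 1 - spec$inplaneAmplitude[1] * k
  jxx <- 1 - spec$inplaneAmplitude[2] * k
  if (min(jzz, jyy, jxx) <= 0.05)
    .stopf("deformation amplitudes too large: mapping not invertible")

  model <- .phantomSceneModel(spec)

  eiScene <- .phantomHuAt(spec, model, as.vector(zm), as.vector(ym),
                          as.vector(xm))
  ei <- array(eiScene$hu, d)
  lung <- array(eiScene$lung, d)

  # EE(y) = scene(phi^{-1}(y)) by fixed-point inversion of phi(x) = x + u(x)
  pz <- zm; py <- ym; px <- xm
  for (it in 1:25) {
    u <- .phantomU(spec, pz, py, px)
    pz <- zm - u$uz; py <- ym - u$uy; px <- xm - u$ux
  }
  ee <- array(.phantomHuAt(spec, model, as.vector(pz), as.vector(py),
                           as.vector(px))$hu, d)

  # planted emphysema: exact voxel count at <= -950 HU among non-vessel
  # lung parenchyma on the EI grid, mirrored to the deformed EE position
  paren <- lung & ei <= spec$parenchymaHu + spec$textureClip &
    ei >= spec$parenchymaHu - spec$textureClip
  nEmph <- round(spec$emphysemaFraction * sum(lung))
  emphIdx <- sample(which(paren), nEmph)
  emphHu <- runif(nEmph, -1000, -962)
  ei[emphIdx] <- emphHu
  uE <- .phantomU(spec, zm[emphIdx], ym[emphIdx], xm[emphIdx])
  ez <- round((zm[emphIdx] + uE$uz) / sp[1]) + 1
  ey <- round((ym[emphIdx] + uE$uy) / sp[2]) + 1
  ex <- round((xm[emphIdx] + uE$ux) / sp[3]) + 1
  ok <- ez >= 1 & ez <= d[1] & ey >= 1 & ey <= d[2] & ex >= 1 & ex <= d[3]
  ee[cbind(ez, ey, ex)[ok, , drop = FALSE]] <- emphHu[ok]

  noise <- function() {
    e <- array(rnorm(prod(d), 0, spec$noiseSd), d)
    pmin(pmax(e, -2 * spec$noiseSd), 2 * spec$noiseSd)
  }
  if (spec$noiseSd > 0) {
    ei <- ei + noise()
    ee <- ee + noise()
  }

  uTrue <- .phantomU(spec, zm, ym, xm)
  strain <- .phantomStrainFields(spec, ym, xm)

  # landmarks: the bright landmark vessels, alternating lungs
  V <- model$vessels
  lmAll <- V[V[, "landmark"] == 1, , drop = FALSE]
  nh <- ceiling(spec$nLandmarks / 2)
  ordAlt <- as.vector(rbind(seq_len(nh), nh + seq_len(nh)))
  lm <- lmAll[ordAlt[seq_len(min(spec$nLandmarks, nrow(lmAll)))], ,
              drop = FALSE]
  lmu <- .phantomU(spec, lm[, 1], lm[, 2], lm[, 3])
  landmarksEI <- data.frame(id = seq_len(nrow(lm)), z = lm[, 1],
                            y = lm[, 2], x = lm[, 3])
  landmarksEE <- data.frame(id = landmarksEI$id, z = lm[, 1] + lmu$uz,
                            y = lm[, 2] + lmu$uy, x = lm[, 3] + lmu$ux)

  out <- list(
    EI = CTVolume(ei, sp, phase = "EI"),
    EE = CTVolume(ee, sp, phase = "EE"),
    truthMask = LungMask(lung * 1, sp),
    dispTrue = new("DisplacementField", uy = array(uTrue$uy, d),
                   ux = array(uTrue$ux, d), spacing = sp, dt = spec$dt),
    uzTrue = array(uTrue$uz, d),
    strainTrue = new("StrainTensorField", eyy = strain$eyy,
                     eyx = strain$eyx, exx = strain$exx, spacing = sp),
    landmarksEI = landmarksEI, landmarksEE = landmarksEE,
    lungVolumeMl = 2 * 4 / 3 * pi * prod(spec$lungSemiaxes) / 1000,
    emphysemaPercentTrue = 100 * nEmph / sum(lung),
    spec = spec)
  class(out) <- "PhantomTruth"
  out
}

#' Sinusoidally inflating phantom phase series
#'
#' A simple multi-phase companion to \code{\link{makePhantom}}: lung
#' ellipsoids whose volume varies sinusoidally over the respiratory cycle
#' (maximal at cycle fraction 0), used to exercise extreme-phase selection.
#'
#' @param spec a \code{\link{phantomSpec}} (geometry and HU are reused).
#' @param nPhases number of phases, default 10.
#' @param inflationAmplitude relative semi-axis modulation, default 0.08.
#' @return list: \code{series} (\linkS4class{PhaseSeries}), \code{masks}
#'   (list of \linkS4class{LungMask}), \code{indexEITrue},
#'   \code{indexEETrue}.
#' @export
makePhantomSeries <- function(spec = phantomSpec(), nPhases = 10,
                              inflationAmplitude = 0.08) {
  d <- spec$shape; sp <- spec$spacing
  g <- .indexGrid(d)
  zm <- (g$z - 1) * sp[1]; ym <- (g$y - 1) * sp[2]; xm <- (g$x - 1) * sp[3]
  fr <- (seq_len(nPhases) - 1) / nPhases
  scale <- 1 + inflationAmplitude * cos(2 * pi * fr)
  vols <- list(); masks <- list()
  for (i in seq_len(nPhases)) {
    li <- .insideEllipsoid(zm, ym, xm, spec$lungCentres[[1]],
                           spec$lungSemiaxes * scale[i]) |
      .insideEllipsoid(zm, ym, xm, spec$lungCentres[[2]],
                       spec$lungSemiaxes * scale[i])
    hu <- array(30, d)
    hu[li] <- spec$parenchymaHu
    vols[[i]] <- CTVolume(hu, sp, phase = sprintf("%.0f%%", 100 * fr[i]))
    masks[[i]] <- LungMask(li * 1, sp)
  }
  list(series = PhaseSeries(vols, fr), masks = masks,
       indexEITrue = which.max(scale), indexEETrue = which.min(scale))
}
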