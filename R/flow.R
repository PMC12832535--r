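#' Farneback optical-flow parameters
#'
#' The canonical seven-parameter 2-D interface, plus the two-fold
#' downsampling used for the initial coarse estimate. Defaults are the
#' analysis settings used throughout: pyramid scale 0.5, 3 pyramid levels,
#' 15-pixel averaging window, 3 iterations per level, polynomial
#' neighbourhood 5 with sigma 1.2, flags 0 (box-filter averaging).
#'
#' @param pyrScale pyramid downscale per level, in (0, 1).
#' @param levels pyramid levels (>= 1).
#' @param winsize odd averaging window, >= 3.
#' @param iterations iterations per pyramid level.
#' @param polyN polynomial-expansion neighbourhood half-width.
#' @param polySigma Gaussian applicability sigma for the expansion.
#' @param flags must be 0 (only the box-averaging variant is provided).
#' @param presmoothDownsample initial coarse-pass downsampling factor.
#' @return a validated \code{FlowParams} list.
#' @export
flowParams <- function(pyrScale = 0.5, levels = 3, winsize = 15,
                       iterations = 3, polyN = 5, polySigma = 1.2,
                       flags = 0, presmoothDownsample = 2) {
  stopifnot(pyrScale > 0, pyrScale < 1, levels >= 1,
            winsize >= 3, winsize %% 2 == 1, iterations >= 1,
            polyN >= 2, polySigma > 0, flags == 0,
            presmoothDownsample >= 1)
  structure(list(pyrScale = pyrScale, levels = as.integer(levels),
                 winsize = as.integer(winsize),
                 iterations = as.integer(iterations),
                 polyN = as.integer(polyN), polySigma = polySigma,
                 flags = as.integer(flags),
                 presmoothDownsample = as.integer(presmoothDownsample)),
            class = "FlowParams")
}

#' Normalize HU to an 8-bit intensity scale for optical flow
#'
#' Linear map of HU clamped to \code{window} onto [0, 255], rounded to
#' integers with R's round-half-to-even rule (so the window midpoint -412 HU
#' maps to 128). The scaling constants depend only on the window, never on
#' the volume, so both members of a phase pair are scaled identically.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param window HU pair (min, max), default (-1024, 200).
#' @return a \linkS4class{CTVolume} whose voxels are in [0, 255].
#' @export
normalizeForFlow <- function(vol, window = c(-1024, 200)) {
  stopifnot(window[1] < window[2])
  v <- pmin(pmax(vol@voxels, window[1]), window[2])
  v <- round((v - window[1]) / (window[2] - window[1]) * 255)
  CTVolume(array(v, dim(vol@voxels)), vol@spacing, vol@origin, vol@phase)
}

# --- 2-D Farneback machinery ------------------------------------------------

# Quadratic polynomial expansion f(x) ~ x'Ax + b'x + c over a Gaussian
# applicability of half-width n, constant certainty. Returns per-pixel
# A11 (= a_yy), A12, A22 (= a_xx), b1 (= b_y), b2 (= b_x).
.polyExp <- function(img, n, sigma) {
  t <- -n:n
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  xg <- t * g; xxg <- t^2 * g
  m2 <- sum(t^2 * g); m4 <- sum(t^4 * g)
  m00 <- .corAxis2d(.corAxis2d(img, g, 1L), g, 2L)
  m10 <- .corAxis2d(.corAxis2d(img, g, 1L), xg, 2L)
  m01 <- .corAxis2d(.corAxis2d(img, xg, 1L), g, 2L)
  m20 <- .corAxis2d(.corAxis2d(img, g, 1L), xxg, 2L)
  m02 <- .corAxis2d(.corAxis2d(img, xxg, 1L), g, 2L)
  m11 <- .corAxis2d(.corAxis2d(img, xg, 1L), xg, 2L)
  den <- m4 - m2^2
  list(A11 = (m02 - m2 * m00) / den,       # a_yy
       A22 = (m20 - m2 * m00) / den,       # a_xx
       A12 = m11 / (2 * m2^2),
       b1 = m01 / m2,                      # b_y
       b2 = m10 / m2)                      # b_x
}

.boxBlur <- function(mat, winsize) {
  k <- rep(1 / winsize, winsize)
  .corAxis2d(.corAxis2d(mat, k, 1L), k, 2L)
}

# One pyramid level: update flow (dy, dx) by `iterations` fixed-point steps.
.flowIterate <- function(E1, E2, dy, dx, winsize, iterations) {
  ny <- nrow(E1$A11); nx <- ncol(E1$A11)
  yg <- matrix(seq_len(ny), ny, nx)
  xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (it in seq_len(iterations)) {
    ys <- yg + dy; xs <- xg + dx
    A11 <- (E1$A11 + .bilinear(E2$A11, ys, xs)) / 2
    A12 <- (E1$A12 + .bilinear(E2$A12, ys, xs)) / 2
    A22 <- (E1$A22 + .bilinear(E2$A22, ys, xs)) / 2
    db1 <- -0.5 * (.bilinear(E2$b1, ys, xs) - E1$b1) + A11 * dy + A12 * dx
    db2 <- -0.5 * (.bilinear(E2$b2, ys, xs) - E1$b2) + A12 * dy + A22 * dx
    G11 <- .boxBlur(A11^2 + A12^2, winsize)
    G12 <- .boxBlur(A12 * (A11 + A22), winsize)
    G22 <- .boxBlur(A12^2 + A22^2, winsize)
    h1 <- .boxBlur(A11 * db1 + A12 * db2, winsize)
    h2 <- .boxBlur(A12 * db1 + A22 * db2, winsize)
    det <- G11 * G22 - G12^2
    ok <- is.finite(det) & det > 1e-12
    dy <- ifelse(ok, (G22 * h1 - G12 * h2) / det, 0)
    dx <- ifelse(ok, (G11 * h2 - G12 * h1) / det, 0)
    dim(dy) <- dim(dx) <- c(ny, nx)
  }
  list(dy = dy, dx = dx)
}

.scaleImage <- function(mat, scale) {
  if (scale >= 1) return(mat)
  sigma <- 0.6 * (1 / scale - 1) + 0.3
  sm <- .sepConv2d(mat, .gaussKernel(sigma), .gaussKernel(sigma))
  .resizeBilinear(sm, pmax(2L, as.integer(round(dim(mat) * scale))))
}

# Dense 2-D flow between two equal-size matrices (pixel units): returns
# (dy, dx) such that from(x) ~ to(x + d(x)). Coarse-to-fine over the
# pyramid, preceded by the presmooth-downsample coarse pass.
.farneback2d <- function(from, to, params) {
  stopifnot(identical(dim(from), dim(to)))
  if (min(dim(from)) < params$winsize)
    .stopf("slice smaller than the %d-pixel flow window", params$winsize)
  base <- 1 / params$presmoothDownsample
  scales <- c(1, base * params$pyrScale^(seq_len(params$levels) - 1))
  scales <- sort(unique(pmin(scales, 1)))   # coarsest level first
  dy <- dx <- NULL
  for (s in scales) {
    f1 <- .scaleImage(from, s); f2 <- .scaleImage(to, s)
    if (min(dim(f1)) < 2 * params$polyN + 1) next
    if (is.null(dy)) {
      dy <- matrix(0, nrow(f1), ncol(f1)); dx <- dy
    } else {
      ry <- nrow(f1) / nrow(dy); rx <- ncol(f1) / ncol(dx)
      dy <- .resizeBilinear(dy, dim(f1)) * ry
      dx <- .resizeBilinear(dx, dim(f1)) * rx
    }
    E1 <- .polyExp(f1, params$polyN, params$polySigma)
    E2 <- .polyExp(f2, params$polyN, params$polySigma)
    res <- .flowIterate(E1, E2, dy, dx, params$winsize, params$iterations)
    dy <- res$dy; dx <- res$dx
  }
  list(dy = dy, dx = dx)
}

#' Dense slice-wise Farneback optical flow between two CT volumes
#'
#' Computes a dense in-plane displacement field on every axial slice by
#' polynomial-expansion optical flow with a coarse-to-fine pyramid; the
#' initial estimate is formed on two-fold downsampled slices and refined at
#' full resolution. Volumes are expected to be rigidly aligned beforehand.
#' The convention is \code{from(x) ~ to(x + u(x))}: \code{u} is the motion
#' of tissue from \code{from} to \code{to}, converted from pixels to mm via
#' the in-plane spacing.
#'
#' @param from,to aligned \linkS4class{CTVolume}s of identical shape
#'   (e.g. end-inspiration and end-expiration).
#' @param params a \code{\link{flowParams}} object.
#' @param dt inter-phase interval in seconds (default 2.0, half a nominal
#'   4 s respiratory cycle).
#' @param sliceRange optional integer vector of z slices to process; other
#'   slices get zero flow. Restricting to lung-bearing slices saves time
#'   without changing masked statistics.
#' @param window HU display window for \code{\link{normalizeForFlow}}.
#' @return a \linkS4class{DisplacementField} (mm).
#' @export
farnebackFlow <- function(from, to, params = flowParams(), dt = 2.0,
                          sliceRange = NULL, window = c(-1024, 200)) {
  stopifnot(identical(dim(from@voxels), dim(to@voxels)))
  d <- dim(from@voxels)
  a <- normalizeForFlow(from, window)@voxels
  b <- normalizeForFlow(to, window)@voxels
  if (is.null(sliceRange)) sliceRange <- seq_len(d[1])
  uy <- array(0, d); ux <- array(0, d)
  for (z in sliceRange) {
    fl <- .farneback2d(a[z, , ], b[z, , ], params)
    uy[z, , ] <- fl$dy * from@spacing[2]
    ux[z, , ] <- fl$dx * from@spacing[3]
  }
  new("DisplacementField", uy = uy, ux = ux, spacing = from@spacing, dt = dt)
}
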