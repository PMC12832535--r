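# Shared numerical kernels: correlation along one axis of a matrix/array with
# replicated borders, Gaussian kernels, bilinear/trilinear sampling, and
# bilinear resizing. All are vectorised; loops only over axes.

# Correlation matrix operator: out[i] = sum_t k[t+r+1] * f[i+t], t in -r..r,
# with edge-replicated padding. Returns the dense (n x (n+2r)) operator.
.corOperator <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  A <- matrix(0, n, n + 2L * r)
  # row i covers padded columns i..i+2r
  idx <- cbind(rep(seq_len(n), each = length(k)),
               rep(seq_len(n), each = length(k)) +
                 rep(seq_along(k) - 1L, times = n))
  A[idx] <- rep(k, times = n)
  A
}

.padReplicate <- function(mat, r, axis) {
  if (r == 0L) return(mat)
  if (axis == 1L) {
    rbind(mat[rep(1L, r), , drop = FALSE], mat,
          mat[rep(nrow(mat), r), , drop = FALSE])
  } else {
    cbind(mat[, rep(1L, r), drop = FALSE], mat,
          mat[, rep(ncol(mat), r), drop = FALSE])
  }
}

# Correlate a 2-D matrix with a 1-D kernel along rows (axis 1) or columns
# (axis 2), replicated borders.
.corAxis2d <- function(mat, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  if (axis == 1L) {
    .corOperator(nrow(mat), k) %*% .padReplicate(mat, r, 1L)
  } else {
    t(.corOperator(ncol(mat), k) %*% t(.padReplicate(mat, r, 2L)))
  }
}

.sepConv2d <- function(mat, ky, kx) .corAxis2d(.corAxis2d(mat, ky, 1L), kx, 2L)

# Correlate a 3-D array with a 1-D kernel along one axis, replicated borders.
.corAxis3d <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) %/% 2L
  m <- .corOperator(da[1], k) %*% .padReplicate(m, r, 1L)
  a <- array(m, da)
  aperm(a, order(perm))
}

.gaussKernel <- function(sigma, r = max(1L, ceiling(3 * sigma))) {
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

.smooth3d <- function(arr, sigma) {
  g <- .gaussKernel(sigma)
  .corAxis3d(.corAxis3d(.corAxis3d(arr, g, 1L), g, 2L), g, 3L)
}

# Bilinear sampling of a matrix at continuous 1-based (yi, xi); coordinates
# outside the grid are clamped to the border.
.bilinear <- function(mat, yi, xi) {
  ny <- nrow(mat); nx <- ncol(mat)
  yi <- pmin(pmax(yi, 1), ny); xi <- pmin(pmax(xi, 1), nx)
  y0 <- pmin(floor(yi), ny - 1L); x0 <- pmin(floor(xi), nx - 1L)
  fy <- yi - y0; fx <- xi - x0
  i00 <- y0 + (x0 - 1) * ny
  v00 <- mat[i00]; v10 <- mat[i00 + 1]
  v01 <- mat[i00 + ny]; v11 <- mat[i00 + ny + 1]
  (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
    (1 - fy) * fx * v01 + fy * fx * v11
}

# Trilinear sampling of a 3-D array at continuous 1-based (zi, yi, xi).
# Out-of-range samples take `fill`; nearest-neighbour available for masks.
.trilinear <- function(arr, zi, yi, xi, fill = -1000,
                       method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr); nz <- d[1]; ny <- d[2]; nx <- d[3]
  outside <- zi < 1 | zi > nz | yi < 1 | yi > ny | xi < 1 | xi > nx
  zi <- pmin(pmax(zi, 1), nz); yi <- pmin(pmax(yi, 1), ny)
  xi <- pmin(pmax(xi, 1), nx)
  if (method == "nearest") {
    v <- arr[cbind(round(zi), round(yi), round(xi))]
  } else {
    z0 <- pmin(floor(zi), nz - 1L); y0 <- pmin(floor(yi), ny - 1L)
    x0 <- pmin(floor(xi), nx - 1L)
    fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
    i000 <- z0 + (y0 - 1) * nz + (x0 - 1) * nz * ny
    sz <- 1L; sy <- nz; sx <- nz * ny
    v <- (1 - fz) * (1 - fy) * (1 - fx) * arr[i000] +
      fz       * (1 - fy) * (1 - fx) * arr[i000 + sz] +
      (1 - fz) * fy       * (1 - fx) * arr[i000 + sy] +
      fz       * fy       * (1 - fx) * arr[i000 + sy + sz] +
      (1 - fz) * (1 - fy) * fx       * arr[i000 + sx] +
      fz       * (1 - fy) * fx       * arr[i000 + sx + sz] +
      (1 - fz) * fy       * fx       * arr[i000 + sx + sy] +
      fz       * fy       * fx       * arr[i000 + sx + sy + sz]
  }
  v[outside] <- fill
  v
}

# Bilinear resize of a matrix to a new shape (centre-aligned sampling).
.resizeBilinear <- function(mat, newdim) {
  ny <- newdim[1]; nx <- newdim[2]
  yi <- (seq_len(ny) - 0.5) * nrow(mat) / ny + 0.5
  xi <- (seq_len(nx) - 0.5) * ncol(mat) / nx + 0.5
  g <- expand.grid(y = yi, x = xi)
  matrix(.bilinear(mat, g$y, g$x), ny, nx)
}

# Voxel-centre coordinate grids (1-based index space) for a dim vector.
.indexGrid <- function(d) {
  list(z = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       x = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
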