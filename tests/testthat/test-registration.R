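test_that("centroid translation recovers constructed shifts", {
  sp <- c(2, 1, 1)
  arr <- array(0, c(20, 30, 30)); arr[6:10, 10:15, 10:15] <- 1
  m <- LungMask(arr, sp)
  expect_equal(centroidTranslation(m, m), c(0, 0, 0))

  # moving = fixed translated by (+6, 0, -4) mm -> shift (-6, 0, +4)
  arr2 <- array(0, c(20, 30, 30)); arr2[9:13, 10:15, 6:11] <- 1
  expect_equal(centroidTranslation(m, LungMask(arr2, sp)), c(-6, 0, 4))

  expect_error(centroidTranslation(m, LungMask(array(0, dim(arr)), sp)),
               "empty mask")
})

test_that("applyTranslation behaves as output(x) = input(x - t)", {
  v <- randomVolume(dims = c(8, 10, 10), seed = 6)
  expect_identical(applyTranslation(v, c(0, 0, 0)), v)

  # integer-voxel shift with nearest: exact permutation plus -1000 fill
  t <- c(2.5, 1.5, -3)   # (1, 1, -2) voxels at spacing (2.5, 1.5, 1.5)
  w <- applyTranslation(v, t, "nearest")
  expect_equal(voxels(w)[2:8, 2:10, 1:8], voxels(v)[1:7, 1:9, 3:10])
  expect_true(all(voxels(w)[1, , ] == -1000))
  expect_true(all(voxels(w)[, , 9:10] == -1000))

  # smooth (band-limited) volume: shift then inverse shift ~ identity
  d <- c(12, 16, 16)
  g <- lungstrain:::.indexGrid(d)
  sm <- CTVolume(array(-800 + 30 * sin(g$x / 5) * cos(g$y / 5), d),
                 c(2.5, 1.5, 1.5))
  rt <- applyTranslation(applyTranslation(sm, c(1.1, 0.7, -0.9)),
                         -c(1.1, 0.7, -0.9))
  inner <- abs(voxels(rt) - voxels(sm))[3:10, 3:14, 3:14]
  expect_lt(mean(inner), 1)
})

test_that("MI refinement recovers a known shift and never scores below init", {
  set.seed(12)
  d <- c(24, 40, 40)
  noise <- array(rnorm(prod(d)), d)
  tex <- lungstrain:::.smooth3d(noise, 1.2)
  tex <- -800 + 300 * tex / sd(tex)
  fixed <- CTVolume(tex, c(2.5, 1.5, 1.5))
  # moving = fixed content moved by (+1, +2, -1) voxels; the aligning
  # shift (applyTranslation convention) is therefore the negative of that
  mv <- array(-1000, d)
  mv[2:24, 3:40, 1:39] <- tex[1:23, 1:38, 2:40]
  moving <- CTVolume(mv, c(2.5, 1.5, 1.5))
  r <- refineTranslationMi(fixed, moving, init = c(0, 0, 0))
  expect_false(r$usedInit)
  expect_gte(r$mi, r$miInit)
  err <- abs(r$shift - c(-2.5, -3, 1.5)) / c(2.5, 1.5, 1.5)
  expect_lt(max(err), 0.5)

  # identity: converges near zero from a small offset
  r0 <- refineTranslationMi(fixed, fixed, init = c(0.4, -0.4, 0.4))
  expect_lt(sqrt(sum(r0$shift^2)), 1)
  expect_gte(r0$mi, r0$miInit)
})

test_that("textureless volumes keep the init with a warning", {
  flat <- CTVolume(array(-500, c(6, 8, 8)), c(2.5, 1.5, 1.5))
  expect_warning(r <- refineTranslationMi(flat, flat, init = c(1, 0, 0)),
                 "textureless")
  expect_true(r$usedInit)
  expect_equal(r$shift, c(1, 0, 0))
})

test_that("TRE reporting is exact, symmetric, and rigid-motion invariant", {
  pts <- data.frame(id = 1:6, z = runif(6, 0, 50), y = runif(6, 0, 80),
                    x = runif(6, 0, 80))
  tre0 <- computeTre(pts, pts)
  expect_true(tre0$pass)
  expect_equal(tre0$maxError, 0)

  off <- pts; off$x[3] <- off$x[3] + 3
  tre <- computeTre(pts, off)
  expect_equal(tre$maxError, 3)
  expect_false(tre$pass)
  # symmetry
  expect_equal(computeTre(off, pts)$perLandmarkError[order(pts$id)],
               tre$perLandmarkError[order(pts$id)])

  # global rigid motion applied to both sets leaves errors unchanged
  th <- 0.4
  rot <- function(p) data.frame(id = p$id, z = p$z + 5,
                                y = cos(th) * p$y - sin(th) * p$x,
                                x = sin(th) * p$y + cos(th) * p$x)
  expect_equal(computeTre(rot(pts), rot(off))$maxError, 3, tolerance = 1e-9)

  bad <- off; bad$id[1] <- 99
  expect_error(computeTre(pts, bad), "id sets")
})
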