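test_that("thresholding marks exactly the voxels at or below the cutoff", {
  sp <- c(2.5, 1.5, 1.5)
  lo <- CTVolume(array(-1000, c(4, 4, 4)), sp)
  hi <- CTVolume(array(0, c(4, 4, 4)), sp)
  expect_true(all(voxels(thresholdLungs(lo)) == 1))
  expect_true(all(voxels(thresholdLungs(hi)) == 0))
  mixed <- CTVolume(array(c(-400, -399.99), c(4, 4, 4)), sp)
  expect_equal(sum(voxels(thresholdLungs(mixed))), 32)
})

test_that("component filtering drops small and boundary components", {
  sp <- c(1, 1, 1)
  arr <- array(0, c(30, 30, 30))
  arr[8:24, 8:24, 8:24] <- 1                 # interior blob, 17^3 = 4913
  m1 <- filterComponents(LungMask(arr, sp), minSizeVoxels = 1000)
  expect_identical(m1@mask, arr)

  arr2 <- arr
  arr2[1:6, 1:30, 1:30] <- 1                 # slab touching the boundary
  m2 <- filterComponents(LungMask(arr2, sp), minSizeVoxels = 1000)
  expect_identical(m2@mask, arr)

  arr3 <- arr
  arr3[27, 27, 27] <- 1                      # speck below the size floor
  m3 <- filterComponents(LungMask(arr3, sp), minSizeVoxels = 1000)
  expect_identical(m3@mask, arr)

  expect_error(filterComponents(LungMask(array(0, c(5, 5, 5)), sp)),
               "empty segmentation")
})

# brute-force ball morphology oracle on a small grid
.bruteBall <- function(mask, r, op) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  out <- array(if (op == "dilate") 0 else 1, d)
  idx <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  for (i in seq_len(nrow(idx))) {
    nb <- sweep(offs, 2, idx[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    vals <- mask[nb[ok, , drop = FALSE]]
    out[idx[i, , drop = FALSE]] <-
      if (op == "dilate") as.numeric(any(vals > 0))
      else as.numeric(all(vals > 0))  # erosion ignores out-of-grid (border)
  }
  out
}

test_that("ball closing matches a brute-force dilate-then-erode oracle", {
  set.seed(21)
  sp <- c(1, 1, 1)
  arr <- array(0, c(14, 14, 14))
  arr[4:11, 4:11, 4:11] <- 1
  arr[4:11, 7:8, 4:11] <- 0                  # 2-voxel slit through the block
  m <- LungMask(arr, sp)
  got <- closeMask(m, radiusVoxels = 2)
  dil <- .bruteBall(arr, 2, "dilate")
  ero <- .bruteBall(dil, 2, "erode")
  # interior comparison: border handling differs only at the grid edge
  expect_identical(got@mask[3:12, 3:12, 3:12], ero[3:12, 3:12, 3:12])
  expect_true(all(got@mask[arr > 0] == 1))   # extensive
  # the slit interior is filled; its open mouths at the block surface
  # remain concave, as closing should leave them
  expect_true(all(got@mask[6:9, 7:8, 6:9] == 1))
})

test_that("closing leaves convex solids and empty masks unchanged", {
  sp <- c(1, 1, 1)
  d <- c(20, 20, 20)
  g <- lungstrain:::.indexGrid(d)
  ball <- ((g$z - 10)^2 + (g$y - 10)^2 + (g$x - 10)^2 <= 36) * 1
  expect_identical(closeMask(LungMask(ball, sp), 3)@mask, ball)
  empty <- LungMask(array(0, c(6, 6, 6)), sp)
  expect_identical(closeMask(empty, 5)@mask, empty@mask)
})

test_that("hole filling solidifies shells and is monotone", {
  sp <- c(1, 1, 1)
  d <- c(20, 20, 20)
  g <- lungstrain:::.indexGrid(d)
  r2 <- (g$z - 10)^2 + (g$y - 10)^2 + (g$x - 10)^2
  shell <- (r2 <= 49 & r2 >= 25) * 1
  solid <- (r2 <= 49) * 1
  expect_identical(fillHoles(LungMask(shell, sp))@mask, solid)
  expect_identical(fillHoles(LungMask(solid, sp))@mask, solid)
})

test_that("closing and hole filling never remove voxels", {
  set.seed(31)
  for (rep in 1:5) {
    arr <- array(0, c(16, 16, 16))
    for (b in 1:4) {
      c0 <- sample(4:13, 3, replace = TRUE)
      arr[(c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2),
          (c0[3] - 2):(c0[3] + 2)] <- 1
    }
    m <- LungMask(arr, c(1, 1, 1))
    expect_true(all(closeMask(m, 2)@mask >= arr))
    expect_true(all(fillHoles(m)@mask >= arr))
  }
})

test_that("phantom segmentation keeps two lungs and matches truth", {
  ph <- getSmallPhantom()
  thr <- filterComponents(thresholdLungs(ph$EI))
  expect_equal(countComponents(thr), 2)
  seg <- segmentLungs(ph$EI)
  expect_gte(diceCoefficient(seg, ph$truthMask), 0.95)

  expect_error(segmentLungs(CTVolume(array(30, c(8, 8, 8)),
                                     c(2.5, 1.5, 1.5))),
               "empty segmentation")
})

test_that("segmentLungs equals its explicit four-step composition", {
  ph <- getSmallPhantom()
  manual <- fillHoles(closeMask(filterComponents(
    thresholdLungs(ph$EI, -400), 1000, TRUE), 5))
  expect_identical(segmentLungs(ph$EI)@mask, manual@mask)
})

test_that("air speckles below the size floor are excluded from the mask", {
  ph <- getSmallPhantom()
  v <- voxels(ph$EI)
  # 200-voxel air pocket planted in the body wall
  v[4:8, 4:11, 60:64] <- -1000
  seg <- segmentLungs(CTVolume(v, voxelSpacing(ph$EI)))
  expect_equal(sum(seg@mask[4:8, 4:11, 60:64]), 0)
})

test_that("mask volume converts voxel counts to millilitres", {
  arr <- array(0, c(10, 10, 10)); arr[1:10, 1:10, 1:10][1:1000] <- 1
  expect_equal(maskVolumeMl(LungMask(arr, c(1, 1, 1))), 1.0)
  expect_equal(maskVolumeMl(LungMask(array(0, c(4, 4, 4)), c(1, 1, 1))), 0)
  ph <- getSmallPhantom()
  expect_lt(abs(maskVolumeMl(ph$truthMask) - ph$lungVolumeMl) /
              ph$lungVolumeMl, 0.02)
})
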