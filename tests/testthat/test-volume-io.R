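test_that("NIfTI save/load round-trips voxels and geometry exactly", {
  v <- randomVolume(seed = 2)
  f <- tempfile(fileext = ".nii.gz")
  saveVolume(v, f)
  w <- loadVolume(f, "nifti")
  expect_identical(voxels(w), voxels(v))
  expect_equal(voxelSpacing(w), voxelSpacing(v))
  expect_equal(voxelOrigin(w), voxelOrigin(v))

  m <- LungMask((voxels(v) > -500) * 1, voxelSpacing(v), voxelOrigin(v))
  fm <- tempfile(fileext = ".nii.gz")
  saveVolume(m, fm)
  m2 <- loadMask(fm)
  expect_identical(m2@mask, m@mask)
})

test_that("written NIfTI is readable by an independent reader", {
  skip_if_not_installed("oro.nifti")
  v <- randomVolume(dims = c(5, 6, 7), seed = 3)
  f <- tempfile(fileext = ".nii.gz")
  saveVolume(v, f)
  img <- oro.nifti::readNIfTI(f, reorient = FALSE)
  expect_equal(dim(img), c(7, 6, 5))                       # x, y, z
  expect_equal(oro.nifti::pixdim(img)[2:4], c(1.5, 1.5, 2.5))
  expect_equal(aperm(array(img@.Data, dim(img)), c(3, 2, 1)),
               voxels(v), tolerance = 1e-12)
})

test_that("saved-then-loaded phantom segments identically to the original", {
  ph <- getSmallPhantom()
  f <- tempfile(fileext = ".nii.gz")
  saveVolume(ph$EI, f)
  again <- loadVolume(f, "nifti")
  expect_identical(voxels(segmentLungs(again)),
                   voxels(segmentLungs(ph$EI)))
})

test_that("resampling preserves constants, ramps, and geometry", {
  v <- randomVolume(seed = 4)
  expect_identical(resampleVolume(v, 1), v)

  const <- CTVolume(array(-850, c(16, 16, 16)), c(2, 2, 2))
  half <- resampleVolume(const, 0.5)
  expect_equal(dim(voxels(half)), c(8L, 8L, 8L))
  expect_equal(voxelSpacing(half), c(4, 4, 4))
  expect_true(all(abs(voxels(half) + 850) < 1e-9))

  # linear ramp: trilinear interpolation is exact at interior centres
  d <- c(8, 8, 32)
  g <- lungstrain:::.indexGrid(d)
  ramp <- CTVolume(array(-1000 + 5 * (g$x - 1) * 1.5, d), c(2.5, 1.5, 1.5))
  rs <- resampleVolume(ramp, 0.5, "linear")
  gx <- lungstrain:::.indexGrid(dim(voxels(rs)))$x
  expected <- -1000 + 5 * (voxelOrigin(rs)[3] + (gx - 1) *
                             voxelSpacing(rs)[3])
  inner <- voxels(rs)[, , 2:15]
  expect_lt(max(abs(inner - expected[, , 2:15])), 1e-6)

  expect_error(resampleVolume(const, 0.05), "axis below 2")
  expect_error(resampleVolume(const, 5), "factor")
})

test_that("down-up resampling of a smooth volume stays within 1 HU", {
  d <- c(16, 24, 24)
  g <- lungstrain:::.indexGrid(d)
  # band-limited: wavelength 48 voxels, well above the Nyquist limit of
  # the downsampled grid
  smooth <- CTVolume(array(-800 + 60 * sin(2 * pi * g$x / 48) *
                             cos(2 * pi * g$y / 48), d), c(2.5, 1.5, 1.5))
  back <- resampleVolume(resampleVolume(smooth, 0.5), 2)
  inner <- abs(voxels(back) - voxels(smooth))[3:14, 4:21, 4:21]
  expect_lt(mean(inner), 1)
})

test_that("extreme phases are selected by measured lung volume", {
  sp <- c(2, 2, 2)
  mk <- function(n) {
    arr <- array(0, c(6, 6, 6)); arr[2:3, 2:3, seq_len(n)] <- 1
    LungMask(arr, sp)
  }
  vols <- lapply(1:5, function(i)
    CTVolume(array(-800, c(6, 6, 6)), sp, phase = sprintf("%d0%%", i - 1)))
  series <- PhaseSeries(vols, seq(0, 0.4, by = 0.1))

  # strictly decreasing volumes: EI first, EE last
  sel <- selectExtremePhases(series, lapply(5:1, mk))
  expect_equal(sel$indexEI, 1)
  expect_equal(sel$indexEE, 5)
  expect_equal(phaseLabel(sel$EI), "EI")

  # all equal: tie broken to the first phase, with a warning
  expect_warning(selT <- selectExtremePhases(series,
                                             lapply(rep(3, 5), mk)), "tie")
  expect_equal(selT$indexEI, 1)
  expect_equal(selT$indexEE, 1)

  expect_error(selectExtremePhases(PhaseSeries(vols[1], 0), list(mk(2))),
               "at least 2")
})

test_that("sinusoidal inflation series yields the generator's extrema", {
  ps <- makePhantomSeries(smallPhantomSpec(), nPhases = 6)
  sel <- selectExtremePhases(ps$series, ps$masks)
  expect_equal(sel$indexEI, ps$indexEITrue)
  expect_equal(sel$indexEE, ps$indexEETrue)
})
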