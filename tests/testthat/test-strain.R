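.mkDisp <- function(uy, ux, sp = c(2.5, 1.5, 1.5), dt = 2) {
  new("DisplacementField", uy = uy, ux = ux, spacing = sp, dt = dt)
}

test_that("central differences are exact on affine displacement fields", {
  d <- c(3, 12, 14)
  sp <- c(2.5, 1.5, 1.5)
  g <- lungstrain:::.indexGrid(d)
  ymm <- (g$y - 1) * sp[2]; xmm <- (g$x - 1) * sp[3]
  a <- 0.07; b <- -0.04
  tens <- strainTensors(.mkDisp(a * ymm, b * xmm, sp))
  expect_equal(max(abs(tens@eyy - a)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tens@exx - b)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tens@eyx)), 0, tolerance = 1e-12)

  # pure shear: u = (c x, c y) -> off-diagonal c, zero diagonal
  cc <- 0.05
  sh <- strainTensors(.mkDisp(cc * xmm, cc * ymm, sp))
  expect_equal(max(abs(sh@eyx - cc)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sh@eyy)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sh@exx)), 0, tolerance = 1e-12)

  # general affine: computed tensor equals sym(grad u) everywhere interior
  uy <- 0.03 * ymm - 0.02 * xmm
  ux <- 0.01 * ymm + 0.06 * xmm
  tg <- strainTensors(.mkDisp(uy, ux, sp))
  expect_equal(max(abs(tg@eyy - 0.03)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tg@exx - 0.06)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tg@eyx - (-0.02 + 0.01) / 2)), 0, tolerance = 1e-12)
})

test_that("zero displacement gives zero strain and zero summaries", {
  d <- c(3, 10, 10)
  disp <- .mkDisp(array(0, d), array(0, d))
  tens <- strainTensors(disp)
  expect_true(all(tens@eyy == 0 & tens@eyx == 0 & tens@exx == 0))
  mask <- LungMask(array(1, d), disp@spacing)
  s <- strainSummary(principalStrains(tens), disp, mask)
  expect_equal(s@PSmax, 0)
  expect_equal(s@PSmean, 0)
  expect_equal(s@Speedmax, 0)
})

test_that("closed-form eigenvalues match a generic eigensolver", {
  set.seed(17)
  d <- c(1, 20, 10)
  eyy <- array(rnorm(prod(d)), d)
  eyx <- array(rnorm(prod(d)), d)
  exx <- array(rnorm(prod(d)), d)
  tens <- new("StrainTensorField", eyy = eyy, eyx = eyx, exx = exx,
              spacing = c(2.5, 1.5, 1.5))
  eig <- principalStrains(tens)
  for (i in sample(prod(d), 60)) {
    ev <- eigen(matrix(c(eyy[i], eyx[i], eyx[i], exx[i]), 2, 2),
                symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(eig$l1[i] - ev[1]), 1e-10)
    expect_lt(abs(eig$l2[i] - ev[2]), 1e-10)
  }
  expect_true(all(eig$l1 >= eig$l2))
  # pure shear s -> eigenvalues +/- s
  ps <- principalStrains(new("StrainTensorField",
                             eyy = array(0, d), eyx = array(0.3, d),
                             exx = array(0, d), spacing = c(2.5, 1.5, 1.5)))
  expect_equal(unique(as.vector(ps$l1)), 0.3)
  expect_equal(unique(as.vector(ps$l2)), -0.3)
})

test_that("eigenvalues are invariant under in-plane frame rotation", {
  set.seed(23)
  for (th in c(0.3, 1.1, 2.5)) {
    E <- matrix(c(rnorm(1), s <- rnorm(1), s, rnorm(1)), 2, 2)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Er <- R %*% E %*% t(R)
    d <- c(1, 2, 2)
    mk <- function(M) new("StrainTensorField",
                          eyy = array(M[1, 1], d), eyx = array(M[1, 2], d),
                          exx = array(M[2, 2], d),
                          spacing = c(2.5, 1.5, 1.5))
    e1 <- principalStrains(mk(E)); e2 <- principalStrains(mk(Er))
    expect_lt(max(abs(e1$l1 - e2$l1)), 1e-10)
    expect_lt(max(abs(e1$l2 - e2$l2)), 1e-10)
  }
})

test_that("rigid translation yields zero strain and Speedmax = |t|/dt", {
  d <- c(3, 10, 12)
  t <- c(1.8, -2.4)   # (y, x) mm
  disp <- .mkDisp(array(t[1], d), array(t[2], d), dt = 2)
  mask <- LungMask(array(1, d), disp@spacing)
  s <- strainSummary(principalStrains(strainTensors(disp)), disp, mask)
  expect_equal(s@Speedmax, sqrt(sum(t^2)) / 2, tolerance = 1e-12)
  expect_lt(abs(s@dimensionlessPSmax), 1e-12)

  # doubling dt halves Speedmax exactly
  disp4 <- .mkDisp(array(t[1], d), array(t[2], d), dt = 4)
  s4 <- strainSummary(principalStrains(strainTensors(disp4)), disp4, mask)
  expect_equal(s4@Speedmax * 2, s@Speedmax, tolerance = 1e-14)
})

test_that("summary scaling, masking and baseline shift behave as stated", {
  d <- c(2, 8, 8)
  sp <- c(2.5, 1.5, 1.5)
  g <- lungstrain:::.indexGrid(d)
  disp <- .mkDisp(0.1 * (g$y - 1) * sp[2], array(0, d), sp, dt = 2)
  mask <- LungMask(array(1, d), sp)
  eigs <- principalStrains(strainTensors(disp))
  smm <- strainSummary(eigs, disp, mask, scaleMode = "paper_mm")
  sdl <- strainSummary(eigs, disp, mask, scaleMode = "dimensionless")
  expect_equal(smm@dimensionlessPSmax, sdl@PSmax)
  expect_equal(smm@PSmax, sdl@PSmax * mean(sp[2:3]))
  expect_gte(smm@PSmax, smm@PSmean)

  # baseline shift enters the speed statistic only
  sb <- strainSummary(eigs, disp, mask, baselineShift = c(0, 3))
  expect_gt(sb@Speedmax, smm@Speedmax)
  expect_equal(sb@PSmax, smm@PSmax)

  expect_error(strainSummary(eigs, disp,
                             LungMask(array(0, d), sp)), "empty mask")
})

test_that("displacement smoothing preserves constants and damps noise", {
  d <- c(4, 20, 20)
  const <- .mkDisp(array(2, d), array(-1, d))
  smc <- smoothDisplacementField(const)
  expect_equal(max(abs(smc@uy - 2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(smc@ux + 1)), 0, tolerance = 1e-9)

  set.seed(3)
  noisy <- .mkDisp(array(rnorm(prod(d)), d), array(rnorm(prod(d)), d))
  smn <- smoothDisplacementField(noisy)
  expect_lt(sd(smn@uy), 0.5 * sd(noisy@uy))
  expect_identical(smoothDisplacementField(noisy, c(0, 0, 0)), noisy)
})
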