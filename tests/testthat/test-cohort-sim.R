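test_that("cohort simulation is deterministic given the seed", {
  sp <- cohortSpec(nNormal = 40, nCopd = 15, seed = 9)
  a <- simulateCohort(sp)
  b <- simulateCohort(sp)
  expect_identical(a, b)
  c2 <- simulateCohort(cohortSpec(nNormal = 40, nCopd = 15, seed = 10))
  expect_false(identical(a$speedmax, c2$speedmax))
})

test_that("group labels are GOLD-consistent with the drawn FEV1/FVC", {
  co <- simulateCohort(cohortSpec(nNormal = 300, nCopd = 120, seed = 2))
  expect_true(all(co$fev1_fvc[co$copd == 1] < 70))
  expect_true(all(co$fev1_fvc[co$copd == 0] >= 70))
  expect_true(all(co$mmrc[co$dyspnea == 1] >= 2))
  expect_true(all(co$mmrc[co$dyspnea == 0] < 2))
})

test_that("marginal means and SDs match the study summaries at large n", {
  co <- simulateCohort(cohortSpec(nNormal = 10000, nCopd = 10000, seed = 5))
  marg <- lungstrain:::.cohortMarginals()
  for (i in seq_len(nrow(marg))) {
    v <- marg$var[i]
    for (grp in c("normal", "copd")) {
      x <- co[[v]][co$group == grp]
      m <- if (grp == "normal") marg$meanNormal[i] else marg$meanCopd[i]
      s <- if (grp == "normal") marg$sdNormal[i] else marg$sdCopd[i]
      expect_lt(abs(mean(x) - m), 3 * s / sqrt(10000) + 0.002 * abs(m) + 1e-6)
      expect_lt(abs(sd(x) - s) / s, 0.05)
    }
  }
  # binary rates
  expect_lt(abs(mean(co$male[co$copd == 0]) - 0.794), 0.02)
  expect_lt(abs(mean(co$dyspnea[co$copd == 1]) - 0.75), 0.02)
})

test_that("effect sizes round-trip through the generator", {
  co <- simulateCohort(cohortSpec(nNormal = 50000, nCopd = 50000, seed = 4))
  dSpeed <- cohensDSamples(co$speedmax[co$copd == 0],
                           co$speedmax[co$copd == 1])
  implied <- cohensD(1074.19, 319.68, 50000, 763.22, 85.22, 50000)
  expect_lt(abs(dSpeed - implied), 0.02)
})

test_that("zeroed correlation targets produce within-group independence", {
  # a pooled correlation cannot be zeroed while group means differ, so
  # zero targets are within-group statements (calibratePooled = FALSE)
  sp <- cohortSpec(nNormal = 1000, nCopd = 1000,
                   targetSpearman = c(fev1_fvc = 0, fev1 = 0, mef50 = 0,
                                      fvc = 0),
                   calibratePooled = FALSE, seed = 6)
  co <- simulateCohort(sp)
  # tolerance covers sampling error (~1/sqrt(n)) plus the small shift a
  # positive-definiteness repair can introduce
  for (v in c("fev1_fvc", "fev1", "mef50", "fvc")) {
    for (grp in c("normal", "copd")) {
      s <- co$group == grp
      expect_lt(abs(spearmanCorr(co$speedmax[s], co[[v]][s])$rho), 0.1)
    }
  }
})

test_that("pooled Speedmax rank correlations hit the stated targets", {
  co <- simulateCohort(cohortSpec(nNormal = 2000, nCopd = 2000, seed = 3))
  targets <- c(fev1_fvc = 0.533, fev1 = 0.445, mef50 = 0.525, fvc = 0.351)
  for (v in names(targets))
    expect_lt(abs(spearmanCorr(co$speedmax, co[[v]])$rho - targets[[v]]),
              0.05)
})

test_that("infeasible correlation targets raise a spec error", {
  sp <- cohortSpec(nNormal = 100, nCopd = 100,
                   targetSpearman = c(fev1_fvc = 0.999), seed = 1)
  expect_error(simulateCohort(sp), "infeasible")
})
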