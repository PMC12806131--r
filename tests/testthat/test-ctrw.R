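test_that("telomere geometry validates and exposes the threshold", {
  expect_equal(shortenThreshold(defaultCfg), 7000)
  expect_error(telomereConfig(l0 = 100, lc = 200), "exceed")
  expect_error(telomereConfig(l0 = 100, lc = -1), "nonnegative")
})

test_that("a vanishing threshold absorbs at the first division", {
  cfg <- telomereConfig(l0 = 1e-9, lc = 0)
  tr <- simulateTrajectory(defaultJump, paretoWait(1.4, 1), cfg,
                           horizon = 1e4, seed = 8)
  expect_true(tr@absorbed)
  expect_length(tr@epochs, 1L)
  expect_equal(tr@absorptionTime, tr@epochs[1L])
})

test_that("a horizon below the wait support yields an untouched telomere", {
  tr <- simulateTrajectory(defaultJump, paretoWait(1.4, 1), defaultCfg,
                           horizon = 0.5, seed = 8)
  expect_length(tr@epochs, 0L)
  expect_false(tr@absorbed)
  expect_equal(evaluateTrajectory(tr, c(0, 0.25, 0.5)), c(0, 0, 0))
})

test_that("divisions to senescence follow the Wald threshold/mean-jump count", {
  ens <- simulateEnsemble(defaultJump, paretoWait(1.4, 1), defaultCfg,
                          horizon = 1000, n = 1e4, seed = 13)
  nre <- lengths(ens@epochs)[ens@absorbed]
  expect_lt(abs(mean(nre) - 7000 / 215), 1)
})

test_that("step evaluation is right-continuous and frozen after absorption", {
  tr <- simulateTrajectory(defaultJump, paretoWait(1.4, 1), defaultCfg,
                           horizon = 500, seed = 3)
  expect_true(tr@absorbed)
  e1 <- tr@epochs[1L]
  expect_equal(evaluateTrajectory(tr, e1 - 1e-9), 0)
  expect_equal(evaluateTrajectory(tr, e1), tr@lengths[1L])
  expect_equal(evaluateTrajectory(tr, 500),
               tr@lengths[length(tr@lengths)])
  expect_error(evaluateTrajectory(tr, 501), "within")
})

test_that("occupation time integrates the step structure exactly", {
  tr <- new("Trajectory", epochs = c(2, 5, 9), lengths = c(10, 25, 40),
            absorbed = FALSE, absorptionTime = NA_real_, horizon = 12)
  ## full band: indicator always 1 up to tObs
  expect_equal(occupationTime(tr, c(0, 1e6), tObs = 7), 7)
  ## band [20, 30): only the level-25 segment [5, 9)
  expect_equal(occupationTime(tr, c(20, 30), tObs = 12), 4)
  expect_equal(occupationTime(tr, c(20, 30), tObs = 6), 1)
  ## all levels below the band
  expect_equal(occupationTime(tr, c(100, 200)), 0)
  ## empty band
  expect_equal(occupationTime(tr, c(5, 5)), 0)
})

test_that("first passage records the leapover epoch or a censored marker", {
  tr <- new("Trajectory", epochs = 5, lengths = 20, absorbed = FALSE,
            absorptionTime = NA_real_, horizon = 10)
  expect_equal(firstPassageTime(tr, 10), 5)   # single jump of twice the level
  expect_true(is.na(firstPassageTime(tr, 30)))
})

test_that("occupation and first passage coincide on monotone absorbed paths", {
  ens <- simulateEnsemble(defaultJump, paretoWait(1.4, 1), defaultCfg,
                          horizon = 1000, n = 1e4, seed = 17)
  tp <- occupationTimes(ens, c(0, 7000))
  tf <- firstPassageTimes(ens)
  ok <- !is.na(tf)
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(tp[ok] - tf[ok])), 1e-8)
  ## censored paths occupy the band for the whole horizon
  expect_true(all(tp[!ok] == ens@horizon))
  ## mass balance at every time
  for (t in c(10, 100, 500, 1000)) {
    nAbs <- sum(ens@absorbed & ens@absorptionTime <= t)
    nAlive <- sum(!is.na(ensembleLengthsAt(ens, t)))
    expect_equal(nAbs + nAlive, trajectoryCount(ens))
  }
})

test_that("generic functionals reduce to the occupation time and constants", {
  tr <- simulateTrajectory(defaultJump, paretoWait(1.4, 1), defaultCfg,
                           horizon = 300, seed = 5)
  expect_equal(pathFunctional(tr, function(l) rep(1, length(l)), 250), 250)
  expect_equal(pathFunctional(tr, function(l) rep(0, length(l)), 250), 0)
  U <- function(l) as.numeric(l >= 0 & l < 7000)
  expect_identical(pathFunctional(tr, U, 250), occupationTime(tr, c(0, 7000), 250))
})

test_that("renewal counts obey the law of large numbers for finite-mean waits", {
  w <- paretoWait(1.8, 1)          # T = 2.25; the O(t^(2-alpha)) renewal
  tEnd <- 2250                     # correction is ~0.6% at t = 1000 T
  ens <- simulateEnsemble(defaultJump, w, defaultCfg, horizon = tEnd, n = 200,
                          absorb = FALSE, seed = 23)
  rate <- mean(lengths(ens@epochs)) / tEnd
  expect_lt(abs(rate * waitMean(w) - 1), 0.02)
})

test_that("ensembles and length grids are reproducible from their seed", {
  a <- simulateEnsemble(defaultJump, paretoWait(1.4, 1), defaultCfg,
                        horizon = 200, n = 50, seed = 99)
  b <- simulateEnsemble(defaultJump, paretoWait(1.4, 1), defaultCfg,
                        horizon = 200, n = 50, seed = 99)
  expect_identical(a@lengths, b@lengths)
  g1 <- simulateLengthGrid(defaultJump, powerLawWait(0.7), c(10, 100), 20,
                           seed = 7)
  g2 <- simulateLengthGrid(defaultJump, powerLawWait(0.7), c(10, 100), 20,
                           seed = 7)
  expect_identical(g1@L, g2@L)
})
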