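test_that("Gruenwald-Letnikov weights reproduce the fractional binomials", {
  nu <- 0.35
  k <- 0:8
  expect_equal(glWeights(nu, 9), (-1)^k * choose(nu, k))
})

test_that("the RL scheme matches closed-form fractional derivatives of powers", {
  dt <- 1e-3
  tg <- seq(0, 1, by = dt)
  for (nu in c(0.3, 0.6)) {
    for (beta in c(1, 2)) {
      out <- riemannLiouville(tg^beta, nu, dt)
      exact <- gamma(beta + 1) / gamma(beta + 1 - nu) * tg^(beta - nu)
      expect_lt(abs(out[length(tg)] / exact[length(tg)] - 1), 0.01)
    }
  }
  ## near-zero order acts as the identity
  f <- sin(tg)
  expect_lt(max(abs(riemannLiouville(f, 1e-7, dt) - f)), 1e-5)
  expect_equal(riemannLiouville(numeric(100), 0.4, dt), numeric(100))
  expect_error(riemannLiouville(f, 1.2, dt), "order")
})

test_that("the substantial derivative is the tilted RL scheme", {
  dt <- 1e-3
  tg <- seq(0, 1, by = dt)
  f <- exp(-0.4 * tg) * tg^2
  ## the tilt commutes with the RL derivative of the power
  out <- substantialDerivative(f, 0.3, dt, tilt = 0.4)
  exact <- exp(-0.4 * tg) * gamma(3) / gamma(3 - 0.3) * tg^(2 - 0.3)
  expect_lt(abs(out[length(tg)] / exact[length(tg)] - 1), 0.01)
  ## untilted path is bitwise the RL path
  expect_identical(substantialDerivative(f, 0.3, dt, tilt = 0),
                   riemannLiouville(f, 0.3, dt))
  expect_equal(substantialDerivative(numeric(50), 0.3, dt, 1), numeric(50))
})

test_that("the convection-diffusion regime reproduces the drifting Gaussian", {
  w <- paretoWait(1.1, 0.01)     # T = 0.11, advection 215/T, diffusion 1/(2T)
  Tm <- ctCoefficients(w)[["T"]]
  sol <- solveFPE(defaultJump, w, telomereConfig(l0 = 4000, lc = 0),
                  tMax = 10 * Tm, nL = 4500L, regime = "normal",
                  Lmax = 2250, absorb = FALSE)
  tAct <- sol@times[1L]
  dL <- sol@L[2L] - sol@L[1L]
  gauss <- dnorm(sol@L, 215 * tAct / Tm, sqrt(tAct / Tm))
  expect_lt(sum(abs(sol@p[, 1L] - gauss)) * dL, 1e-2)
  expect_lt(abs(sum(sol@p[, 1L]) * dL - 1), 1e-6)
})

test_that("survival mass starts at one, never grows, and stays positive", {
  sol <- solveFPE(defaultJump, powerLawWait(0.7), defaultCfg, tMax = 60,
                  nL = 100L, regime = "subdiffusive",
                  snapshotTimes = c(20, 60))
  expect_lt(sol@survival[1L], 1 + 1e-9)
  expect_true(all(diff(sol@survival) < 1e-12))
  expect_gte(min(sol@p), 0)
  expect_equal(survivalFromFPE(sol, 0), 1)
  expect_lt(abs(survivalFromFPE(sol, 60) - sum(sol@p[, 2L]) * (sol@L[2L] - sol@L[1L])),
            1e-9)
})

test_that("refinement converges at the scheme's first-order rate", {
  ## dt-refinement of the subdiffusive scheme against a fine reference
  run <- function(dt) solveFPE(defaultJump, powerLawWait(0.7), defaultCfg,
                               tMax = 5, nL = 80L, regime = "subdiffusive",
                               dt = dt)@p[, 1L]
  ref <- run(0.00625)
  e1 <- sum(abs(run(0.025) - ref))
  e2 <- sum(abs(run(0.0125) - ref))
  order <- log2(e1 / e2)
  expect_gt(order, 0.8)
  ## dL-refinement of the normal regime against the Gaussian closed form
  w <- paretoWait(1.1, 0.01)
  Tm <- ctCoefficients(w)[["T"]]
  gerr <- function(nL) {
    sol <- solveFPE(defaultJump, w, telomereConfig(l0 = 4000, lc = 0),
                    tMax = 10 * Tm, nL = nL, regime = "normal", Lmax = 2250,
                    absorb = FALSE)
    dL <- sol@L[2L] - sol@L[1L]
    sum(abs(sol@p[, 1L] - dnorm(sol@L, 215 * sol@times[1L] / Tm,
                                sqrt(sol@times[1L] / Tm)))) * dL
  }
  expect_gt(log2(gerr(1125) / gerr(2250)), 0.8)
})

test_that("unstable configurations are refused with a diagnostic", {
  expect_error(solveFPE(defaultJump, powerLawWait(0.7), defaultCfg, tMax = 10,
                        nL = 400L, regime = "subdiffusive", dt = 0.5),
               "stability")
  expect_error(solveFPE(defaultJump, powerLawWait(0.7), defaultCfg, tMax = 10,
                        regime = "normal"), "subdiffusive")
})
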