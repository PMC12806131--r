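test_that("closed-form mean matches direct evaluation of the fractional law", {
  j <- defaultJump
  expect_lt(abs(meanAnalytic(powerLawWait(0.5), j, 1) - 215 / gamma(1.5)),
            1e-10)
  expect_lt(meanAnalytic(powerLawWait(0.3), j, 1e-30), 1e-2)  # t^alpha -> 0
  ## Pareto family: limit branches bracket the full expression
  w <- paretoWait(1.4, 1)
  t <- c(10, 100, 1000)
  full <- meanAnalytic(w, j, t)
  expect_true(all(full > meanAnalytic(w, j, t, branch = "normal")))
  expect_true(all(full > meanAnalytic(w, j, t, branch = "fractional")))
  expect_error(meanAnalytic(temperedWait(0.7), j, 1), "power-law")
})

test_that("EAMSD prefactors and branch limits evaluate exactly", {
  j <- defaultJump
  ## alpha = 0.5: prefactor 2/Gamma(2) - 1/Gamma(1.5)^2 = 2 - 4/pi
  w <- powerLawWait(0.5)
  expect_lt(abs(eamsdAnalytic(w, j, 1) -
                  ((2 - 4 / pi) * 215^2 + 1 / gamma(1.5))), 1e-8)
  ## normal branch is exactly linear
  wp <- paretoWait(1.4, 1)
  expect_equal(eamsdAnalytic(wp, j, 20, branch = "normal"),
               2 * eamsdAnalytic(wp, j, 10, branch = "normal"))
  ## exact jump-variance convention adds the Poisson contribution
  expect_gt(eamsdAnalytic(wp, j, 10, branch = "normal", convention = "exact"),
            eamsdAnalytic(wp, j, 10, branch = "normal"))
})

test_that("asymptotic EAMSD has the exact exponent and the full form converges", {
  j <- defaultJump
  w <- powerLawWait(0.4)
  tt <- exp(seq(log(1e3), log(1e4), length.out = 20))
  asym <- new("MomentCurve", times = tt, values = eamsdAsymptotic(w, j, tt),
              kind = "eamsd", source = "analytic", fit = list())
  expect_lt(abs(fitLogLogSlope(asym)$slope - 0.8), 1e-12)
  full <- new("MomentCurve", times = tt, values = eamsdAnalytic(w, j, tt),
              kind = "eamsd", source = "analytic", fit = list())
  expect_lt(abs(fitLogLogSlope(full)$slope - 0.8), 1e-2)
  ## ratio approaches 1 monotonically beyond the crossover
  ratio <- eamsdAnalytic(w, j, tt) / eamsdAsymptotic(w, j, tt)
  expect_true(all(ratio >= 1))
  expect_true(all(diff(abs(ratio - 1)) < 0))
})

test_that("log-log fitting is exact on power laws and guards its window", {
  tt <- exp(seq(log(10), log(1000), length.out = 25))
  curve <- new("MomentCurve", times = tt, values = 3.7 * tt^1.23,
               kind = "eamsd", source = "analytic", fit = list())
  f <- fitLogLogSlope(curve, c(10, 1000))
  expect_lt(abs(f$slope - 1.23), 1e-12)
  expect_lt(abs(f$intercept - log(3.7)), 1e-10)
  flat <- new("MomentCurve", times = tt, values = rep(2, 25),
              kind = "mean", source = "analytic", fit = list())
  expect_lt(abs(fitLogLogSlope(flat, c(10, 1000))$slope), 1e-12)
  expect_error(fitLogLogSlope(curve, c(900, 1000)), "at least")
  bad <- new("MomentCurve", times = tt, values = c(rep(1, 24), 0),
             kind = "mean", source = "empirical", fit = list())
  expect_error(fitLogLogSlope(bad, c(10, 1000)), "nonpositive")
})

test_that("regime classification reports exponents and the C/T ratio", {
  r <- classifyRegime(powerLawWait(0.4))
  expect_equal(r@regime, "subdiffusive")
  expect_equal(r@exponent, 0.8)
  expect_equal(classifyRegime(powerLawWait(0.7))@regime, "superdiffusive")
  ## independent arithmetic: C/T = |Gamma(1-a)| tau0^a (a-1) / (a tau0)
  rC <- classifyRegime(paretoWait(1.1, 0.01))
  expect_lt(abs(rC@ctRatio -
                  abs(gamma(-0.1)) * 0.01^1.1 * 0.1 / (1.1 * 0.01)), 1e-12)
  expect_equal(rC@regime, "mixed")          # ratio ~ 0.61 sits between cutoffs
  expect_equal(rC@exponent, 3 - 1.1)
  rE <- classifyRegime(paretoWait(1.8, 1))
  expect_equal(rE@regime, "mixed")          # ratio ~ 2.55
  expect_equal(rE@exponent, 1.2)
  ## forcing the cutoffs selects the limit branches
  expect_equal(classifyRegime(paretoWait(1.1, 0.01), cutoffs = c(1, 10))@exponent, 1)
  expect_equal(classifyRegime(paretoWait(1.8, 1), cutoffs = c(0.01, 1))@exponent,
               4 - 2 * 1.8)
  ## tempered: relative to the tempering horizon
  expect_equal(classifyRegime(temperedWait(0.7, 1, 0.1), horizon = 2000)@regime,
               "normal")
  expect_equal(classifyRegime(temperedWait(0.7, 1, 0.1), horizon = 2)@exponent,
               1.4)
  expect_error(classifyRegime(temperedWait(0.7, 1, 0.1)), "horizon")
})

test_that("empirical EAMSD recovers the superdiffusive exponent", {
  times <- exp(seq(log(20), log(2e4), length.out = 30))
  gr <- simulateLengthGrid(defaultJump, powerLawWait(0.7), times, n = 2000,
                           seed = 5)
  emp <- eamsdEmpirical(gr)
  expect_lt(abs(fitLogLogSlope(emp)$slope - 1.4), 0.1)
  mn <- meanEmpirical(gr)
  an <- meanAnalytic(powerLawWait(0.7), defaultJump, times)
  expect_lt(max(abs(mn@values / an - 1)[times >= 2000]), 0.05)
})

test_that("empirical and closed-form EAMSD slopes agree in the mixed regime", {
  ## alpha = 1.8: the t^(3-alpha) renewal-fluctuation term dominates the
  ## printed transient exponent 4-2*alpha over this window
  w <- paretoWait(1.8, 1)
  times <- exp(seq(log(200), log(2000), length.out = 15))
  gr <- simulateLengthGrid(defaultJump, w, times, n = 3000, seed = 11)
  empSlope <- fitLogLogSlope(eamsdEmpirical(gr), c(200, 2000))$slope
  an <- new("MomentCurve", times = times,
            values = eamsdAnalytic(w, defaultJump, times),
            kind = "eamsd", source = "analytic", fit = list())
  anSlope <- fitLogLogSlope(an, c(200, 2000))$slope
  expect_lt(abs(empSlope - anSlope), 0.2)
  expect_gt(empSlope, 1)     # far from the 4-2*alpha = 0.4 transient
})

test_that("moment estimation refuses degenerate inputs", {
  g <- simulateLengthGrid(defaultJump, powerLawWait(0.7), c(1, 2), 1, seed = 1)
  expect_error(eamsdEmpirical(g), "at least 2")
  ens <- simulateEnsemble(defaultJump, paretoWait(1.4, 1), defaultCfg,
                          horizon = 100, n = 10, seed = 1)
  expect_error(eamsdEmpirical(ens, times = c(1, 10)), "without absorption")
})
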