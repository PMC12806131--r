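test_that("occupation-time estimates separate interior mass from the atom", {
  ens <- unitStepEnsemble(n = 200L, steps = 10L)
  ## band so wide the path never leaves: all mass in the atom at tObs
  fd <- suppressWarnings(occupationDensityMC(ens, band = c(0, 1e9), tObs = 8))
  expect_equal(fd@atomMass, 1)
  expect_equal(fd@censoredFraction, 1)
  expect_length(fd@mids, 0L)
  ## band [0, 5.5): left at the 6th unit step
  fd2 <- suppressWarnings(occupationDensityMC(ens, band = c(0, 5.5), tObs = 8,
                                              bins = 16L))
  expect_equal(fd2@atomMass, 0)
  expect_equal(sum(fd2@density) * diff(fd2@breaks[1:2]), 1)
  expect_lt(abs(fd2@mids[which.max(fd2@density)] - 6), 0.51)
})

test_that("first-passage densities report censoring honestly", {
  ens <- unitStepEnsemble(n = 200L, steps = 10L)
  fd <- suppressWarnings(fptDensityMC(ens, threshold = 5.5, bins = 21L))
  expect_equal(fd@censoredFraction, 0)
  ## deterministic unit waits and jumps: the sixth division crosses 5.5
  expect_lt(abs(fd@mids[which.max(fd@density)] - 6), 0.51)
  ## unreachable threshold: everything censored
  fd2 <- suppressWarnings(fptDensityMC(ens, threshold = 1e9))
  expect_equal(fd2@censoredFraction, 1)
})

test_that("the survival curve matches the complementary passage distribution", {
  ens <- simulateEnsemble(defaultJump, temperedWait(0.7, 1, 0.1), defaultCfg,
                          horizon = 200, n = 2000, seed = 31)
  tg <- c(0, 20, 40, 60, 100, 150)
  sv <- survivalCurve(ens, tGrid = tg)
  expect_equal(sv[1L], 1)
  expect_true(all(diff(sv) <= 0))
  tf <- firstPassageTimes(ens)
  manual <- vapply(tg, function(t) mean(is.na(tf) | tf > t), numeric(1))
  expect_equal(sv, manual)
  ## survival equals the probability of zero occupation above the threshold
  above <- occupationTimes(ens, c(7000, Inf), 100)
  expect_equal(sv[tg == 100], mean(above == 0))
})

test_that("mode counting sees a single peak through tail noise", {
  mk <- function(y) new("FunctionalDensity", mids = seq_along(y), density = y,
                        breaks = numeric(0), censoredFraction = 0,
                        atom = NA_real_, atomMass = 0, estimator = "histogram",
                        bandwidth = NA_real_, n = 100L)
  expect_equal(countModes(mk(c(0.1, 1, 3, 2, 0.5, 0.2))), 1L)
  expect_equal(countModes(mk(c(0.1, 3, 0.5, 2.5, 0.2))), 2L)
  ## tiny tail ripples below the height floor are ignored
  y <- dnorm(seq(-3, 8, by = 0.1))
  y[80:110] <- y[80:110] + 1e-6 * (1.1 + sin(1:31))
  expect_equal(countModes(mk(y)), 1L)
})

test_that("the backward solver is exact at p = 0 and respects its boundary", {
  sol <- solveBackwardFK(defaultJump, temperedWait(0.7, 1, 0.1),
                         telomereConfig(l0 = 500, lc = 0), p = c(0, 0.5),
                         tMax = 5, nL = 25L)
  expect_lt(max(abs(sol@G[1L, ] - 1)), 1e-12)
  ## a positive transform value decays the functional transform
  expect_true(all(Re(sol@G[2L, -1L]) < 1))
  expect_true(all(Re(sol@G[2L, ]) > 0))
  expect_error(solveBackwardFK(defaultJump, temperedWait(0.7, 1, 0.1),
                               telomereConfig(l0 = 500, lc = 0), p = -1,
                               tMax = 5), "nonnegative")
})

test_that("the backward solver matches MC transforms in its validity regime", {
  ## weak tempering (B^gamma xi^gamma << 1) and a threshold of ~33 mean jumps:
  ## the regime where the macroscopic equation approximates the renewal model
  tw <- temperedWait(0.7, 1, 0.01)
  sol <- solveBackwardFK(defaultJump, tw, defaultCfg,
                         p = c(0.01, 0.02, 0.05), tMax = 250, nL = 70L)
  ens <- simulateEnsemble(defaultJump, tw, defaultCfg, horizon = 250,
                          n = 2e4, seed = 9)
  tp <- occupationTimes(ens, c(0, 7000), 250)
  for (k in 1:3) {
    mc <- mean(exp(-sol@p[k] * tp))
    expect_lt(abs(Re(sol@G[k, ncol(sol@G)]) - mc), 0.04)
  }
})

test_that("Gaver-Stehfest inverts textbook transforms", {
  A <- seq(0.2, 5, by = 0.4)
  expect_lt(max(abs(gaverStehfest(function(p) 1 / (1 + p), A, M = 7) -
                      exp(-A))), 1e-3)
  ## transform of the constant 1
  expect_lt(max(abs(gaverStehfest(function(p) 1 / p, A, M = 6) - 1)), 1e-8)
})

test_that("transform inversion recovers densities from solution objects", {
  ## Laplace mode: a synthetic solution carrying G = 1/(1+p)
  A <- seq(0.5, 4, by = 0.5)
  M <- 7L
  ps <- sort(unique(as.vector(outer(seq_len(2L * M), log(2) / A))))
  sol <- new("FKSolution", p = ps, times = c(0, 1),
             G = matrix(rep(1 / (1 + ps), 2L), ncol = 2L), L0 = 0,
             mode = "laplace", threshold = 500)
  inv <- invertFunctionalTransform(sol, t = 1, A = A, M = M)
  expect_lt(max(abs(inv$density - exp(-A))), 1e-3)
  expect_false(inv$flagged)
  expect_equal(inv$clippedMass, 0)
  ## Fourier mode: shift theorem puts a point mass at the shift
  om <- seq(-40, 40, by = 0.25)
  a <- 2.5
  solF <- new("FKSolution", p = om, times = c(0, 1),
              G = matrix(rep(exp(1i * om * a), 2L), ncol = 2L), L0 = 0,
              mode = "fourier", threshold = 500)
  invF <- invertFunctionalTransform(solF, t = 1,
                                    A = seq(0, 5, length.out = 201))
  expect_equal(invF$A[which.max(invF$density)], a, tolerance = 0.05)
  ## a smooth target additionally conserves mass and shape
  solG <- new("FKSolution", p = om, times = c(0, 1),
              G = matrix(rep(exp(1i * om * a - om^2 * 0.4^2 / 2), 2L),
                         ncol = 2L), L0 = 0, mode = "fourier", threshold = 500)
  invG <- invertFunctionalTransform(solG, t = 1,
                                    A = seq(0, 5, length.out = 201))
  expect_lt(abs(sum(invG$density) * 0.025 - 1), 0.02)
  expect_lt(max(abs(invG$density - dnorm(invG$A, a, 0.4))), 0.01)
})
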