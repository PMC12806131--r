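## Distributions of path functionals: Monte Carlo estimators for occupation
## and first-passage times, and a backward Feynman-Kac solver with the
## tempered fractional substantial derivative for cross-validation.

## ---------------------------------------------------------------------------
## Monte Carlo functional densities
## ---------------------------------------------------------------------------

buildDensity <- function(x, atomAt, atomMass, censored, bins, estimator,
                         upper, n) {
  estimator <- match.arg(estimator, c("histogram", "kernel"))
  if (n < 100L)
    warning("fewer than 100 trajectories: density estimate is unreliable")
  interiorMass <- 1 - atomMass
  if (!length(x)) {
    return(new("FunctionalDensity", mids = numeric(0), density = numeric(0),
               breaks = numeric(0), censoredFraction = censored,
               atom = atomAt, atomMass = atomMass, estimator = estimator,
               bandwidth = NA_real_, n = as.integer(n)))
  }
  if (estimator == "histogram") {
    breaks <- seq(0, upper, length.out = bins + 1L)
    h <- graphics::hist(pmin(x, upper), breaks = breaks, plot = FALSE)
    dens <- h$counts / n / diff(breaks)
    new("FunctionalDensity", mids = h$mids, density = dens, breaks = breaks,
        censoredFraction = censored, atom = atomAt, atomMass = atomMass,
        estimator = "histogram", bandwidth = NA_real_, n = as.integer(n))
  } else {
    bw <- stats::bw.nrd(x)          # Scott's rule
    d <- stats::density(x, bw = bw, from = 0, to = upper, n = max(bins, 256L))
    new("FunctionalDensity", mids = d$x, density = d$y * interiorMass,
        breaks = numeric(0), censoredFraction = censored, atom = atomAt,
        atomMass = atomMass, estimator = "kernel", bandwidth = bw,
        n = as.integer(n))
  }
}

#' Monte Carlo occupation-time density
#'
#' Estimates the density `J` of the occupation time `T+` of a shortening
#' band over `[0, tObs]` from an ensemble. Trajectories that never leave the
#' band by `tObs` have `T+ = tObs` exactly; that probability atom is reported
#' separately (`atomMass`) and the interior density integrates to
#' `1 - atomMass`.
#'
#' @param ens an [Ensemble-class] simulated to a horizon of at least `tObs`
#' @param band shortening band `c(lo, hi)` (default `[0, l0 - lc)`)
#' @param tObs observation time (default the horizon)
#' @param bins number of histogram bins (or kernel grid floor)
#' @param estimator `"histogram"` or `"kernel"` (Scott's-rule bandwidth)
#' @return a [FunctionalDensity-class]
#' @export
occupationDensityMC <- function(ens, band = c(0, shortenThreshold(ens@telomere)),
                                tObs = ens@horizon, bins = 50L,
                                estimator = "histogram") {
  if (tObs > ens@horizon) stop("'tObs' exceeds the simulated horizon")
  tp <- occupationTimes(ens, band, tObs)
  atEnd <- tp >= tObs - 1e-12 * tObs
  buildDensity(tp[!atEnd], tObs, mean(atEnd), mean(atEnd), bins, estimator,
               tObs, length(tp))
}

#' Monte Carlo first-passage-time density
#'
#' Density of the first time the cumulative shortening reaches `threshold`;
#' horizon-censored passages are reported as `censoredFraction` and the
#' interior density integrates to `1 - censoredFraction`.
#'
#' @inheritParams occupationDensityMC
#' @param threshold critical shortening (bp)
#' @return a [FunctionalDensity-class]
#' @export
fptDensityMC <- function(ens, threshold = shortenThreshold(ens@telomere),
                         bins = 50L, estimator = "histogram") {
  tf <- firstPassageTimes(ens, threshold)
  cens <- mean(is.na(tf))
  buildDensity(tf[!is.na(tf)], ens@horizon, cens, cens, bins, estimator,
               ens@horizon, length(tf))
}

#' Monte Carlo survival curve of the first passage time
#'
#' `P(T_f > t)`: for the monotone paths of this model this equals the
#' probability that the running maximum of the shortening stays below the
#' threshold, i.e. the probability that the occupation time of the band
#' `[0, threshold)` at horizon `t` equals `t`.
#'
#' @inheritParams fptDensityMC
#' @param tGrid evaluation times within the horizon
#' @return survival probabilities at `tGrid`
#' @export
survivalCurve <- function(ens, threshold = shortenThreshold(ens@telomere),
                          tGrid) {
  stopifnot(all(tGrid <= ens@horizon))
  tf <- firstPassageTimes(ens, threshold)
  vapply(tGrid, function(t) mean(is.na(tf) | tf > t), numeric(1))
}

#' Count the modes of a functional density estimate
#'
#' Number of local maxima of the density values whose height exceeds
#' `relTol` times the global maximum (maxima in the numerical-noise floor of
#' the tails are ignored); used to verify the single-peak shape of the
#' occupation-time density.
#'
#' @param fd a [FunctionalDensity-class]
#' @param relTol minimum peak height relative to the global maximum
#' @return integer mode count
#' @export
countModes <- function(fd, relTol = 0.05) {
  y <- fd@density
  if (length(y) < 3L) return(as.integer(length(y) > 0))
  floorY <- relTol * max(y)
  peaks <- 0L
  s <- sign(diff(y))
  s[s == 0] <- NA                      # plateaus inherit the previous trend
  for (i in seq_along(s)) if (is.na(s[i])) s[i] <- if (i > 1) s[i - 1] else 1
  for (i in seq_len(length(s) - 1L))
    if (s[i] > 0 && s[i + 1L] < 0 && y[i + 1L] > floorY) peaks <- peaks + 1L
  peaks
}

## ---------------------------------------------------------------------------
## Backward Feynman-Kac solver (tempered waits)
## ---------------------------------------------------------------------------

#' Solve the backward Feynman-Kac equation for an occupation functional
#'
#' Computes `G_{L0}(p, t) = E[exp(-p A)]` (Laplace mode, `A >= 0`) or
#' `E[exp(i p A)]` (Fourier mode) for the functional
#' `A = integral of U(L(tau)) dtau` of the tempered-wait shortening process
#' started at shortening level `L0`, by explicit time stepping of the
#' backward equation with the tempered fractional substantial derivative
#' (Gruenwald-Letnikov with exponentially tilted weights, tilt
#' `xi + p U(L0)` per node in Laplace mode).
#'
#' `U` is the indicator of the band `[0, l0-lc)`: for the monotone paths of
#' this model every starting point at or beyond the threshold has `A = 0`
#' identically, which supplies the exact right boundary value `G = 1`.
#' The advection and diffusion coefficients are
#' `(lambda+mu)(1+B^gamma xi^gamma)/B^gamma` and `sigma^2/(2 B^gamma)`,
#' with the `+xi^gamma` zeroth-order term inside the memory operator.
#' The inhomogeneous term `(xi - xi^gamma D_t^(1-gamma,xi+pU)) exp(-p U t)`
#' is discretised with the same Gruenwald-Letnikov weights as the memory
#' operator so that its `t^(gamma-1)` short-time singularity cancels
#' discretely against the `xi^gamma G` contribution.
#'
#' @param jump a [JumpModel-class]
#' @param wait a [TemperedWait-class]
#' @param cfg a [TelomereConfig-class]
#' @param p transform values: nonnegative reals (Laplace) or reals `omega`
#'   interpreted as `i*omega` (Fourier)
#' @param tMax final time
#' @param nL number of spatial nodes on `[0, l0-lc)`
#' @param dt time step (default from the effective Courant target)
#' @param mode `"laplace"` (default; functional is nonnegative) or
#'   `"fourier"`
#' @param L0 starting shortening level at which `G` is read off (default 0)
#' @param courant target effective Courant number for the automatic `dt`
#' @param convention jump-variance convention, see [eamsdAnalytic()]
#' @return an [FKSolution-class] (`G` is complex in Fourier mode)
#' @export
solveBackwardFK <- function(jump, wait, cfg, p, tMax, nL = 50L, dt = NULL,
                            mode = c("laplace", "fourier"), L0 = 0,
                            courant = 0.4, convention = c("macroscopic", "exact")) {
  mode <- match.arg(mode)
  stopifnot(is(wait, "TemperedWait"))
  if (mode == "laplace" && any(p < 0))
    stop("Laplace mode requires nonnegative transform values")
  g <- wait@gamma; B <- wait@B; xi <- wait@xi
  Bg <- B^g
  a <- jumpMean(jump) * (1 + Bg * xi^g) / Bg
  D <- jumpVar(jump, match.arg(convention)) / (2 * Bg)

  thr <- shortenThreshold(cfg)
  nL <- as.integer(nL)
  dL <- thr / nL
  Lnodes <- (seq_len(nL) - 1L) * dL       # all strictly inside the band
  iL0 <- which.min(abs(Lnodes - L0))

  if (is.null(dt)) {
    f <- function(ldt) {
      s <- exp(ldt)^g
      a * s / dL + 2 * D * s / dL^2 - courant
    }
    dt <- exp(stats::uniroot(f, c(log(1e-12), log(max(tMax, 1))))$root)
    nt <- ceiling(tMax / dt)
    dt <- tMax / nt
  } else {
    nt <- round(tMax / dt)
    if (abs(nt * dt - tMax) > 1e-9 * tMax)
      stop("'tMax' must be an integer multiple of 'dt'")
  }
  cn <- a * dt^g / dL + 2 * D * dt^g / dL^2
  if (cn > 1 + 1e-9)
    stop(sprintf("stability violation: effective Courant number %.3f > 1; reduce dt", cn))

  w <- glWeights(1 - g, nt + 1L)
  dtm <- dt^(g - 1)
  tgrid <- (0:nt) * dt
  cplx <- mode == "fourier"
  Gout <- matrix(if (cplx) complex(1) else numeric(1), length(p), nt + 1L)

  for (ip in seq_along(p)) {
    pv <- p[ip]
    pU <- if (mode == "laplace") pv else -1i * pv   # theta = xi + pU term
    theta <- xi + pU                                 # tilt at U = 1 nodes
    tw <- w * exp(-theta * dt * (0:nt))              # tilted GL weights
    ## discretised source: xi*E(t) - xi^g * GL^(1-g,theta)[E](t),
    ## E(t) = exp(-pU t)
    Ehist <- exp(-pU * tgrid)
    glE <- dtm * convFirstC(Ehist, tw)
    src <- xi * Ehist - xi^g * glE

    G <- rep(if (cplx) 1 + 0i else 1, nL)
    W <- matrix(if (cplx) complex(1) else numeric(1), nL, nt + 1L)
    spatial <- function(G) {
      Gr <- c(G[-1L], 1)          # exact boundary: G = 1 at/beyond threshold
      Gl <- c(G[1L], G[-nL])      # zero-flux at L0 = 0 (diffusion is tiny)
      a * (Gr - G) / dL + D * (Gr - 2 * G + Gl) / dL^2 + xi^g * G
    }
    W[, 1L] <- spatial(G)
    Gout[ip, 1L] <- G[iL0]
    for (n in seq_len(nt)) {
      k <- n
      mem <- dtm * as.vector(W[, n:1, drop = FALSE] %*% tw[seq_len(k)])
      G <- G + dt * (mem - (xi + pU) * G + src[n])
      W[, n + 1L] <- spatial(G)
      Gout[ip, n + 1L] <- G[iL0]
    }
  }

  new("FKSolution", p = as.numeric(p), times = tgrid, G = Gout,
      L0 = Lnodes[iL0], mode = mode, threshold = thr)
}

## complex-capable linear convolution (first length(f) terms)
convFirstC <- function(f, w) {
  if (!is.complex(f) && !is.complex(w)) return(convFirst(f, w))
  n <- length(f)
  m <- stats::nextn(2L * n)
  zf <- c(as.complex(f), complex(m - n))
  zw <- c(as.complex(w[seq_len(n)]), complex(m - n))
  out <- stats::fft(stats::fft(zf) * stats::fft(zw), inverse = TRUE) / m
  out[seq_len(n)]
}

## ---------------------------------------------------------------------------
## Transform inversion
## ---------------------------------------------------------------------------

#' Gaver-Stehfest coefficients
#'
#' @param M half the number of terms (2M evaluations per abscissa)
#' @return numeric vector of 2M coefficients
#' @export
gaverStehfestWeights <- function(M) {
  zeta <- numeric(2L * M)
  for (k in seq_len(2L * M)) {
    j <- seq.int(floor((k + 1) / 2), min(k, M))
    zeta[k] <- (-1)^(M + k) * sum(
      j^(M + 1) / factorial(M) * choose(M, j) * choose(2 * j, j) *
        choose(j, k - j))
  }
  zeta
}

#' Invert a Laplace transform by Gaver-Stehfest
#'
#' `f(A) ~ (ln 2 / A) * sum_k zeta_k * G(k ln2 / A)`. Accurate to roughly
#' `0.8*M` digits for smooth targets when `G` is known to high precision;
#' small `M` (4-5) is advisable when `G` itself carries numerical error.
#'
#' @param Gfun function of the transform variable
#' @param A evaluation points (> 0)
#' @param M half the number of terms
#' @return density values at `A`
#' @export
gaverStehfest <- function(Gfun, A, M = 6L) {
  zeta <- gaverStehfestWeights(M)
  vapply(A, function(a) {
    ps <- seq_len(2L * M) * log(2) / a
    log(2) / a * sum(zeta * Gfun(ps))
  }, numeric(1))
}

#' Invert a Feynman-Kac solution into a functional density
#'
#' Laplace mode: Gaver-Stehfest inversion at each requested functional value
#' `A`; the solution must contain the abscissae `k*ln2/A, k = 1..2M` in its
#' `p` grid (as built by [occupationDensityFK()]). Negative inverted values
#' are clipped at zero and the clipped mass is reported; an oscillation
#' beyond `flagTol` marks the result as flagged.
#' Fourier mode: trapezoidal discrete inverse transform of `G(. , t)` over
#' the symmetric `p` grid.
#'
#' @param sol an [FKSolution-class]
#' @param t time at which to invert (nearest stored step is used)
#' @param A functional values at which to evaluate the density (Laplace mode)
#' @param M Gaver-Stehfest half-order (Laplace mode)
#' @return list with `A`, `density`, `clippedMass` and `flagged`
#' @export
invertFunctionalTransform <- function(sol, t, A = NULL, M = 4L) {
  it <- which.min(abs(sol@times - t))
  if (sol@mode == "fourier") {
    om <- sol@p
    if (is.null(A)) A <- seq(0, max(sol@times), length.out = 200L)
    dOm <- mean(diff(om))
    G <- sol@G[, it]
    dens <- vapply(A, function(a) Re(sum(exp(-1i * om * a) * G)) * dOm / (2 * pi),
                   numeric(1))
    clip <- sum(pmax(-dens, 0) * c(diff(A), 0))
    return(list(A = A, density = pmax(dens, 0), clippedMass = clip,
                flagged = FALSE))
  }
  if (is.null(A)) stop("Laplace mode requires the functional grid 'A'")
  zeta <- gaverStehfestWeights(M)
  dens <- vapply(A, function(a) {
    ps <- seq_len(2L * M) * log(2) / a
    idx <- vapply(ps, function(x) {
      j <- which.min(abs(sol@p - x))
      if (abs(sol@p[j] - x) > 1e-8 * max(x, 1))
        stop("solution lacks the Gaver-Stehfest abscissae for this 'A'; ",
             "use occupationDensityFK() to build a matching solve")
      j
    }, integer(1))
    Re(log(2) / a * sum(zeta * sol@G[idx, it]))
  }, numeric(1))
  neg <- pmax(-dens, 0)
  wA <- c(diff(A), 0)
  clip <- sum(neg * wA)
  ## flag violent sign oscillation (classic Gaver-Stehfest failure mode)
  flagged <- clip > 0.1 || (length(dens) > 2 &&
                              sum(abs(diff(sign(dens))) > 0) > length(dens) / 2)
  list(A = A, density = pmax(dens, 0), clippedMass = clip, flagged = flagged)
}

#' Occupation-time density from the backward Feynman-Kac equation
#'
#' Convenience pipeline: builds the pooled Gaver-Stehfest abscissae for the
#' requested functional values `A`, solves the backward equation once for
#' that transform grid, and inverts at the observation time.
#'
#' @inheritParams solveBackwardFK
#' @param tObs observation time
#' @param A functional values (occupation times) at which to evaluate
#' @param M Gaver-Stehfest half-order (small values are robust to solver
#'   error)
#' @return list with `A`, `density`, `clippedMass`, `flagged` and the
#'   [FKSolution-class] as `solution`
#' @export
occupationDensityFK <- function(jump, wait, cfg, tObs, A, M = 4L, nL = 50L,
                                dt = NULL, courant = 0.4) {
  ps <- sort(unique(as.vector(outer(seq_len(2L * M), log(2) / A))))
  sol <- solveBackwardFK(jump, wait, cfg, p = ps, tMax = tObs, nL = nL,
                         dt = dt, mode = "laplace", courant = courant)
  inv <- invertFunctionalTransform(sol, tObs, A = A, M = M)
  inv$solution <- sol
  inv
}
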