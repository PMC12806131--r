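## Renewal-process engine: trajectories, ensembles, path functionals.

#' Construct the telomere geometry
#'
#' @param l0 initial telomere length (bp)
#' @param lc critical length below which division is limited (bp)
#' @return a [TelomereConfig-class] object; the absorbing threshold for the
#'   cumulative shortening is `l0 - lc`
#' @examples
#' cfg <- telomereConfig()       # threshold 7000 bp
#' shortenThreshold(cfg)
#' @export
telomereConfig <- function(l0 = 10000, lc = 3000) {
  new("TelomereConfig", l0 = as.numeric(l0), lc = as.numeric(lc))
}

#' @rdname telomereConfig
#' @param cfg a [TelomereConfig-class] object
#' @export
shortenThreshold <- function(cfg) cfg@l0 - cfg@lc

## rough expected renewal count by `horizon`, used to size sampling chunks
expectedRenewals <- function(wait, horizon) {
  m <- waitMean(wait)
  if (is.finite(m)) return(horizon / m)
  if (is(wait, "PowerLawWait"))
    return((horizon / wait@t0)^wait@alpha / gamma(1 + wait@alpha))
  (horizon / wait@B)^wait@gamma   # untempered stable
}

## One renewal path as plain vectors; absorption at `threshold` (Inf = off).
simCore <- function(jump, wait, threshold, horizon, chunk) {
  epochs <- numeric(0)
  lens <- numeric(0)
  total <- 0
  cum <- 0
  absorbed <- FALSE
  absTime <- NA_real_
  repeat {
    w <- sampleWait(wait, chunk)
    ep <- total + cumsum(w)
    keep <- ep <= horizon
    nk <- sum(keep)
    if (nk) {
      j <- rnorm(nk, jump@mu, jump@sigma) + rpois(nk, jump@lambda)
      cl <- cum + cumsum(j)
      hit <- which(cl >= threshold)
      if (length(hit)) {
        k <- hit[1L]
        epochs <- c(epochs, ep[seq_len(k)])
        lens <- c(lens, cl[seq_len(k)])
        absorbed <- TRUE
        absTime <- ep[k]
        break
      }
      epochs <- c(epochs, ep[keep])
      lens <- c(lens, cl)
      cum <- cl[nk]
    }
    total <- ep[chunk]
    if (total > horizon) break
  }
  list(epochs = epochs, lengths = lens, absorbed = absorbed, absTime = absTime)
}

#' Simulate one shortening trajectory
#'
#' Alternates waiting times (cell cycles) and shortening jumps; the
#' cumulative loss `L(t)` is a right-continuous step function, constant
#' between divisions. Simulation stops at the horizon or, when `absorb` is
#' `TRUE`, at the first division taking `L` to or past the threshold
#' `l0 - lc` (the final jump may overshoot: leapover).
#'
#' @param jump a [JumpModel-class]
#' @param wait a [WaitingTimeModel-class]
#' @param cfg a [TelomereConfig-class]
#' @param horizon simulation end time (> 0)
#' @param absorb stop at the critical threshold? (default `TRUE`)
#' @param seed optional integer seed
#' @return a [Trajectory-class]
#' @export
simulateTrajectory <- function(jump, wait, cfg, horizon, absorb = TRUE,
                               seed = NULL) {
  stopifnot(horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  thr <- if (absorb) shortenThreshold(cfg) else Inf
  chunk <- max(64L, ceiling(1.25 * min(expectedRenewals(wait, horizon),
                                       if (absorb) 2 * thr / jumpMean(jump) else Inf)) + 16L)
  res <- simCore(jump, wait, thr, horizon, chunk)
  new("Trajectory", epochs = res$epochs, lengths = res$lengths,
      absorbed = res$absorbed, absorptionTime = res$absTime, horizon = horizon)
}

#' Simulate an ensemble of independent trajectories
#'
#' @inheritParams simulateTrajectory
#' @param n number of trajectories
#' @param seed integer seed (required: ensembles are reproducible artefacts)
#' @return an [Ensemble-class]
#' @export
simulateEnsemble <- function(jump, wait, cfg, horizon, n, absorb = TRUE,
                             seed = 1L) {
  stopifnot(horizon > 0)
  n <- checkN(n)
  set.seed(seed)
  thr <- if (absorb) shortenThreshold(cfg) else Inf
  chunk <- max(64L, ceiling(1.25 * min(expectedRenewals(wait, horizon),
                                       if (absorb) 2 * thr / jumpMean(jump) else Inf)) + 16L)
  eps <- vector("list", n)
  lens <- vector("list", n)
  ab <- logical(n)
  at <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- simCore(jump, wait, thr, horizon, chunk)
    eps[[i]] <- res$epochs
    lens[[i]] <- res$lengths
    ab[i] <- res$absorbed
    at[i] <- res$absTime
  }
  new("Ensemble", epochs = eps, lengths = lens, absorbed = ab,
      absorptionTime = at, horizon = horizon, jump = jump, wait = wait,
      telomere = cfg, seed = as.integer(seed))
}

#' @rdname simulateEnsemble
#' @param ens an [Ensemble-class]
#' @param i trajectory index
#' @return `trajectory()` returns the `i`-th [Trajectory-class]
#' @export
trajectory <- function(ens, i) {
  new("Trajectory", epochs = ens@epochs[[i]], lengths = ens@lengths[[i]],
      absorbed = ens@absorbed[i], absorptionTime = ens@absorptionTime[i],
      horizon = ens@horizon)
}

#' @rdname simulateEnsemble
#' @export
trajectoryCount <- function(ens) length(ens@epochs)

#' Simulate ensemble shortening lengths on a time grid
#'
#' Moment-oriented simulation without absorption. Only the renewal counts
#' are simulated path-wise; the jump sums between consecutive grid times are
#' drawn in closed form (a sum of `k` independent Normal+Poisson jumps is
#' `Normal(k*mu, k*sigma^2) + Poisson(k*lambda)`), which reproduces the exact
#' finite-dimensional law of `L` on the grid at a fraction of the cost.
#'
#' @param jump a [JumpModel-class]
#' @param wait a [WaitingTimeModel-class]
#' @param times strictly increasing positive grid
#' @param n number of trajectories
#' @param seed integer seed
#' @return a [LengthGrid-class]
#' @export
simulateLengthGrid <- function(jump, wait, times, n, seed = 1L) {
  stopifnot(length(times) >= 1L, all(times > 0), !is.unsorted(times, strictly = TRUE))
  n <- checkN(n)
  set.seed(seed)
  horizon <- times[length(times)]
  m <- length(times)
  chunk <- max(64L, ceiling(1.25 * expectedRenewals(wait, horizon)) + 16L)
  L <- matrix(0, n, m)
  for (i in seq_len(n)) {
    cw <- cumsum(sampleWait(wait, chunk))
    while (cw[length(cw)] < horizon) {
      w2 <- sampleWait(wait, chunk)
      cw <- c(cw, cw[length(cw)] + cumsum(w2))
    }
    dN <- diff(c(0L, findInterval(times, cw)))
    pos <- dN > 0L
    dL <- numeric(m)
    if (any(pos))
      dL[pos] <- rnorm(sum(pos), jump@mu * dN[pos], jump@sigma * sqrt(dN[pos])) +
        rpois(sum(pos), jump@lambda * dN[pos])
    L[i, ] <- cumsum(dL)
  }
  new("LengthGrid", times = as.numeric(times), L = L, jump = jump, wait = wait,
      seed = as.integer(seed))
}

#' Evaluate a trajectory on a time grid
#'
#' Right-continuous step interpolation: at a division epoch the post-jump
#' value is returned; after absorption the value is held constant.
#'
#' @param traj a [Trajectory-class]
#' @param times evaluation times within `[0, horizon]`
#' @return cumulative shortening lengths at `times`
#' @export
evaluateTrajectory <- function(traj, times) {
  if (any(times < 0) || any(times > traj@horizon))
    stop("'times' must lie within [0, horizon]")
  c(0, traj@lengths)[findInterval(times, traj@epochs) + 1L]
}

## segments of the step path clipped to [0, tObs]:
## starts s_j, durations d_j, levels l_j
pathSegments <- function(traj, tObs) {
  s <- c(0, traj@epochs)
  e <- c(traj@epochs, traj@horizon)
  l <- c(0, traj@lengths)
  d <- pmin(e, tObs) - pmin(s, tObs)
  keep <- d > 0
  list(duration = d[keep], level = l[keep])
}

#' Occupation time of a shortening band
#'
#' Total time the cumulative shortening spends inside `band = [lo, hi)`
#' during `[0, tObs]`, computed exactly from the step structure of the path.
#' With `band = [0, l0 - lc)` this is the occupation-time statistic `T+`;
#' for the monotone paths of this model it equals the first passage time
#' whenever the threshold is reached before `tObs`.
#'
#' @param traj a [Trajectory-class]
#' @param band numeric length-2 interval (closed left, open right)
#' @param tObs observation time (defaults to the horizon)
#' @return occupation time in `[0, tObs]`
#' @export
occupationTime <- function(traj, band, tObs = traj@horizon) {
  if (tObs > traj@horizon) stop("'tObs' must not exceed the horizon")
  if (band[2L] <= band[1L]) return(0)
  ## same quadrature order as pathFunctional() with an indicator U, so the
  ## two agree bitwise
  pathFunctional(traj, function(l) as.numeric(l >= band[1L] & l < band[2L]),
                 tObs)
}

#' First passage time of the critical threshold
#'
#' The first instant the cumulative shortening reaches or exceeds
#' `threshold`. Because paths change only at division epochs, the first
#' passage is always a division epoch and the crossing jump may overshoot
#' the threshold (leapover). Returns `NA` when the threshold is not reached
#' by the horizon (censored; never silently dropped).
#'
#' @param traj a [Trajectory-class]
#' @param threshold positive length (bp)
#' @return first passage time, or `NA_real_` if censored
#' @export
firstPassageTime <- function(traj, threshold) {
  stopifnot(threshold > 0)
  hit <- which(traj@lengths >= threshold)
  if (!length(hit)) return(NA_real_)
  traj@epochs[hit[1L]]
}

#' Generic path functional
#'
#' `A = integral over [0, tObs] of U(L(tau)) dtau`, evaluated exactly as a
#' piecewise-constant quadrature over the step path. Reduces to
#' [occupationTime()] when `U` is the indicator of a band.
#'
#' @param traj a [Trajectory-class]
#' @param U a vectorised function of the shortening level
#' @param tObs observation time (defaults to the horizon)
#' @return the functional value
#' @export
pathFunctional <- function(traj, U, tObs = traj@horizon) {
  if (tObs > traj@horizon) stop("'tObs' must not exceed the horizon")
  seg <- pathSegments(traj, tObs)
  sum(U(seg$level) * seg$duration)
}

## --- vectorised ensemble functionals --------------------------------------

#' Ensemble path functionals
#'
#' Vectorised occupation times, first passage times and grid evaluations
#' over all trajectories of an ensemble.
#'
#' @param ens an [Ensemble-class]
#' @param band,threshold,tObs,t as in the per-trajectory functions
#' @return numeric vector with one entry per trajectory (`NA` marks a
#'   censored first passage)
#' @export
occupationTimes <- function(ens, band, tObs = ens@horizon) {
  if (band[2L] <= band[1L]) return(numeric(length(ens@epochs)))
  vapply(seq_along(ens@epochs), function(i) {
    ep <- ens@epochs[[i]]
    s <- c(0, ep)
    e <- c(ep, ens@horizon)
    l <- c(0, ens@lengths[[i]])
    d <- pmin(e, tObs) - pmin(s, tObs)
    sum(d[d > 0 & l >= band[1L] & l < band[2L]])
  }, numeric(1))
}

#' @rdname occupationTimes
#' @export
firstPassageTimes <- function(ens, threshold = shortenThreshold(ens@telomere)) {
  vapply(seq_along(ens@epochs), function(i) {
    hit <- which(ens@lengths[[i]] >= threshold)
    if (!length(hit)) NA_real_ else ens@epochs[[i]][hit[1L]]
  }, numeric(1))
}

#' @rdname occupationTimes
#' @export
ensembleLengthsAt <- function(ens, t) {
  stopifnot(t >= 0, t <= ens@horizon)
  vapply(seq_along(ens@epochs), function(i) {
    if (ens@absorbed[i] && ens@absorptionTime[i] <= t) return(NA_real_)
    c(0, ens@lengths[[i]])[findInterval(t, ens@epochs[[i]]) + 1L]
  }, numeric(1))
}
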