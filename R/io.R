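## Run configurations, JSON/CSV serialisation, canonical fixtures.

#' Construct a run configuration
#'
#' @param jump a [JumpModel-class]
#' @param wait a [WaitingTimeModel-class]
#' @param telomere a [TelomereConfig-class]
#' @param nTraj ensemble size
#' @param horizon simulation horizon
#' @param seed integer seed
#' @param label free-text label
#' @return a [RunConfig-class]
#' @export
runConfig <- function(jump = jumpModel(), wait = paretoWait(1.4),
                      telomere = telomereConfig(), nTraj = 10000L,
                      horizon = 2000, seed = 1L, label = "run") {
  new("RunConfig", jump = jump, wait = wait, telomere = telomere,
      nTraj = as.integer(nTraj), horizon = as.numeric(horizon),
      seed = as.integer(seed), label = as.character(label))
}

waitToList <- function(wait) {
  if (is(wait, "PowerLawWait"))
    list(family = "power_low", alpha = wait@alpha, t0 = wait@t0)
  else if (is(wait, "ParetoWait"))
    list(family = "pareto_high", alpha = wait@alpha, tau0 = wait@tau0)
  else
    list(family = "tempered", gamma = wait@gamma, B = wait@B, xi = wait@xi)
}

waitFromList <- function(x) {
  if (is.null(x$family))
    stop("waiting_time: missing 'family' (power_low, pareto_high or tempered)")
  switch(x$family,
         power_low = {
           if (is.null(x$alpha)) stop("waiting_time: missing 'alpha'")
           if (is.null(x$t0)) powerLawWait(x$alpha) else powerLawWait(x$alpha, x$t0)
         },
         pareto_high = {
           if (is.null(x$alpha)) stop("waiting_time: missing 'alpha'")
           paretoWait(x$alpha, if (is.null(x$tau0)) 1 else x$tau0)
         },
         tempered = {
           for (f in c("gamma", "B", "xi"))
             if (is.null(x[[f]])) stop(sprintf("waiting_time: missing '%s'", f))
           temperedWait(x$gamma, x$B, x$xi)
         },
         stop(sprintf("waiting_time: unknown family '%s'", x$family)))
}

configToList <- function(cfg) {
  list(jump_length = list(lambda = cfg@jump@lambda, mu = cfg@jump@mu,
                          sigma = cfg@jump@sigma),
       waiting_time = waitToList(cfg@wait),
       telomere = list(l0 = cfg@telomere@l0, lc = cfg@telomere@lc),
       n_traj = cfg@nTraj, horizon = cfg@horizon, seed = cfg@seed,
       label = cfg@label)
}

#' Read and write run configurations as JSON
#'
#' A single schema is shared by all entry points:
#' `jump_length` (`lambda`, `mu`, `sigma`), `waiting_time` (`family` plus its
#' numeric fields), `telomere` (`l0`, `lc`), `n_traj`, `horizon`, `seed`,
#' `label`. Round-trips are lossless; schema violations raise errors naming
#' the offending field.
#'
#' @param cfg a [RunConfig-class]
#' @param path file path
#' @return `readRunConfig()` returns a [RunConfig-class]
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(configToList(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("jump_length", "waiting_time", "telomere"))
    if (is.null(x[[f]])) stop(sprintf("config: missing section '%s'", f))
  for (f in c("lambda", "mu", "sigma"))
    if (is.null(x$jump_length[[f]])) stop(sprintf("jump_length: missing '%s'", f))
  for (f in c("l0", "lc"))
    if (is.null(x$telomere[[f]])) stop(sprintf("telomere: missing '%s'", f))
  runConfig(jump = jumpModel(x$jump_length$lambda, x$jump_length$mu,
                             x$jump_length$sigma),
            wait = waitFromList(x$waiting_time),
            telomere = telomereConfig(x$telomere$l0, x$telomere$lc),
            nTraj = if (is.null(x$n_traj)) 10000L else x$n_traj,
            horizon = if (is.null(x$horizon)) 2000 else x$horizon,
            seed = if (is.null(x$seed)) 1L else x$seed,
            label = if (is.null(x$label)) "run" else x$label)
}

#' Canonical 32-bit hash of a run configuration
#'
#' FNV-1a over the canonical parameter string; changes whenever any model
#' parameter, size, horizon or seed changes. Used to stamp output tables.
#'
#' @param cfg a [RunConfig-class]
#' @return hex string
#' @export
configHash <- function(cfg) {
  l <- configToList(cfg)
  flat <- unlist(l, use.names = TRUE)
  s <- paste(names(flat), vapply(flat, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) sprintf("%.17g", num) else as.character(v)
  }, character(1)), sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  ## FNV-1a with exact 32-bit arithmetic on doubles
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- (h %% 65536) * prime
    hi <- ((h %/% 65536) * prime) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## 32-bit xor for nonnegative doubles below 2^32
xor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

## ---------------------------------------------------------------------------
## Tabular output with a stamped comment header
## ---------------------------------------------------------------------------

writeStamped <- function(df, path, cfg = NULL, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# telosim %s",
                     as.character(utils::packageVersion("telosim"))), con)
  if (!is.null(cfg)) {
    writeLines(sprintf("# config_hash: %s", configHash(cfg)), con)
    writeLines(sprintf("# seed: %d", cfg@seed), con)
  }
  for (e in extra) writeLines(paste0("# ", e), con)
  ## full double precision so tables round-trip exactly
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

readStamped <- function(path, required) {
  df <- utils::read.table(path, sep = ",", header = TRUE, comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  df
}

#' Write and read ensemble tables
#'
#' `writeTrajectoryTable()` stores the long step-path table
#' (`traj_id`, `epoch_time`, `cumulative_shortening`, `absorbed_flag`);
#' `writeEnsembleSummary()` stores per-trajectory functionals
#' (`traj_id`, `t_plus`, `t_f`, `censored`). Both stamp a comment header with
#' package version, config hash and seed; readers validate the schema and
#' name any missing column.
#'
#' @param ens an [Ensemble-class]
#' @param path file path
#' @param cfg optional [RunConfig-class] for the header stamp
#' @return the reader returns a `data.frame`
#' @export
writeTrajectoryTable <- function(ens, path, cfg = NULL) {
  n <- trajectoryCount(ens)
  df <- data.frame(
    traj_id = rep(seq_len(n), lengths(ens@epochs)),
    epoch_time = unlist(ens@epochs),
    cumulative_shortening = unlist(ens@lengths),
    absorbed_flag = rep(ens@absorbed, lengths(ens@epochs)))
  writeStamped(df, path, cfg)
}

#' @rdname writeTrajectoryTable
#' @export
readTrajectoryTable <- function(path) {
  readStamped(path, c("traj_id", "epoch_time", "cumulative_shortening",
                      "absorbed_flag"))
}

#' @rdname writeTrajectoryTable
#' @param band occupation band (default `[0, l0-lc)`)
#' @param tObs observation time for the occupation functional
#' @export
writeEnsembleSummary <- function(ens, path, cfg = NULL,
                                 band = c(0, shortenThreshold(ens@telomere)),
                                 tObs = ens@horizon) {
  tf <- firstPassageTimes(ens, band[2L])
  df <- data.frame(
    traj_id = seq_len(trajectoryCount(ens)),
    t_plus = occupationTimes(ens, band, tObs),
    t_f = tf,
    censored = is.na(tf))
  writeStamped(df, path, cfg,
               extra = sprintf("censored_fraction: %.6f", mean(is.na(tf))))
}

#' @rdname writeTrajectoryTable
#' @export
readEnsembleSummary <- function(path) {
  readStamped(path, c("traj_id", "t_plus", "t_f", "censored"))
}

#' @rdname writeTrajectoryTable
#' @param curve a [MomentCurve-class]
#' @export
writeMomentCurve <- function(curve, path, cfg = NULL) {
  df <- data.frame(t = curve@times, value = curve@values,
                   kind = curve@kind, source = curve@source)
  writeStamped(df, path, cfg)
}

#' @rdname writeTrajectoryTable
#' @export
readMomentCurve <- function(path) {
  df <- readStamped(path, c("t", "value", "kind", "source"))
  momentCurve(df$t, df$value, df$kind[1L], df$source[1L])
}

## ---------------------------------------------------------------------------
## Canonical fixtures
## ---------------------------------------------------------------------------

#' The five canonical diffusion-regime configurations
#'
#' Parameter sets spanning the diffusion regimes of the shortening process,
#' all with the default jump law (`lambda = 155`, `mu = 60`, `sigma = 1`):
#' \describe{
#'   \item{A}{infinite-mean waits, `alpha = 0.4`, horizon `2e4` (subdiffusive,
#'     EAMSD exponent `2*alpha = 0.8`)}
#'   \item{B}{infinite-mean waits, `alpha = 0.7`, horizon `2e4`
#'     (superdiffusive, exponent `1.4`)}
#'   \item{C}{Pareto waits, `alpha = 1.1`, `tau0 = 0.01`, horizon `2e3`
#'     (small `C/T`)}
#'   \item{D}{Pareto waits, `alpha = 1.4`, `tau0 = 1`, horizon `2e3` (mixed,
#'     exponent `3 - alpha = 1.6`)}
#'   \item{E}{Pareto waits, `alpha = 1.8`, `tau0 = 1`, horizon `2e3` (large
#'     `C/T`)}
#' }
#'
#' @param nTraj ensemble size stored in the configs
#' @param seed seed stored in the configs
#' @return named list of five [RunConfig-class] objects
#' @export
diffusionRegimeConfigs <- function(nTraj = 10000L, seed = 1L) {
  mk <- function(wait, horizon, label)
    runConfig(jump = jumpModel(), wait = wait, telomere = telomereConfig(),
              nTraj = nTraj, horizon = horizon, seed = seed, label = label)
  list(A = mk(powerLawWait(0.4), 2e4, "A"),
       B = mk(powerLawWait(0.7), 2e4, "B"),
       C = mk(paretoWait(1.1, 0.01), 2e3, "C"),
       D = mk(paretoWait(1.4, 1), 2e3, "D"),
       E = mk(paretoWait(1.8, 1), 2e3, "E"))
}

#' The canonical tempered occupation-time configuration
#'
#' Tempered waits with tempering rate `xi = 0.1` (stability index and scale
#' at the package defaults `gamma = 0.7`, `B = 1`), default jump law, and the
#' shortening band `[0, 7000]` bp.
#'
#' @inheritParams diffusionRegimeConfigs
#' @param horizon simulation horizon
#' @return a [RunConfig-class]
#' @export
temperedConfig <- function(nTraj = 10000L, horizon = 2000, seed = 1L) {
  runConfig(jump = jumpModel(), wait = temperedWait(gamma = 0.7, B = 1, xi = 0.1),
            telomere = telomereConfig(), nTraj = nTraj, horizon = horizon,
            seed = seed, label = "tempered")
}

#' Run the simulation described by a configuration
#'
#' @param cfg a [RunConfig-class]
#' @param absorb absorbing threshold on/off
#' @return an [Ensemble-class]
#' @export
runEnsemble <- function(cfg, absorb = TRUE) {
  simulateEnsemble(cfg@jump, cfg@wait, cfg@telomere, cfg@horizon, cfg@nTraj,
                   absorb = absorb, seed = cfg@seed)
}
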