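## Stochastic engine: protocols, exact SSA runs, first-passage detection,
## adaptation classification, ensemble statistics.

#' Protocol constructor
#'
#' @param mode `"arrest"` (nUK held fixed), `"washout"` (first-order
#'   kinetochore attachment from t = 0) or `"pulse"` (transient Mps1
#'   overexpression via the mutant window).
#' @param nUK0 initial unattached kinetochores (default 10).
#' @param tMax horizon in minutes; defaults mirror the experiment
#'   durations (700 arrest, 960 washout).
#' @param mutant a [MutantSpec-class] of parameter overrides.
#' @param init `"on"`, `"off"` or a named custom state (8 species,
#'   molecules).
#' @param seed integer run seed.
#' @return a [ProtocolSpec-class].
#' @export
protocolSpec <- function(mode = c("arrest", "washout", "pulse"), nUK0 = 10,
                         tMax = NULL, mutant = mutantSpec(), init = "on",
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(tMax))
    tMax <- switch(mode, arrest = 700, washout = 960, pulse = 600)
  new("ProtocolSpec", mode = mode, nUK0 = nUK0,
      attachment = (mode == "washout"), mutant = mutant, tMax = tMax,
      init = init, seed = as.integer(seed))
}

.initial_state <- function(protocol, params) {
  x <- protocol@init
  if (is.character(x)) x <- referenceState(x, params@unitSystem)
  x <- mutantState(x, protocol@mutant)
  c(round(x[.SPECIES]), ponCDC20 = 1, ponX = 1, nUK = protocol@nUK0)
}

#' Run one exact stochastic simulation
#'
#' Direct-method Gillespie simulation of the full 22-reaction network in
#' molecule units, including two-state (bursting) promoters for Cdc20 and
#' Mps1. Every state component stays a nonnegative integer, the APC and
#' Mad moieties are conserved exactly, and nUK is non-increasing when
#' attachment is enabled. Runs are reproducible given the protocol seed.
#'
#' @param protocol a [ProtocolSpec-class].
#' @param params molecule-unit [CheckpointParams-class].
#' @param recordDt sampling interval for the returned trajectory (min);
#'   `0` records no path (outcome only).
#' @param stopAtCross stop the simulation at the first threshold crossing
#'   (saves work in ensembles).
#' @return a [Trajectory-class]; its `metadata` carries `tCross`,
#'   `nUKAtCross`, `tAllAttached` and the protocol.
#' @export
ssaRun <- function(protocol, params = checkpointParams("molecules"),
                   recordDt = 1, stopAtCross = FALSE) {
  if (params@unitSystem != "molecules")
    stop("the stochastic engine requires molecule-unit parameters")
  p <- applyMutant(params, mutantSpec(
    kassACFactor = protocol@mutant@kassACFactor))
  pw <- protocol@mutant@window
  pulseOn <- protocol@mutant@mps1SynthesisFactor != 1
  x0 <- .initial_state(protocol, params)
  set.seed(protocol@seed)
  res <- .ssa_core(as.numeric(x0), paramValues(p), protocol@tMax,
                   acThreshold(params), protocol@attachment, stopAtCross,
                   recordDt, protocol@mutant@mps1SynthesisFactor,
                   if (pulseOn) max(pw[1], 0) else Inf,
                   if (pulseOn) min(pw[2], protocol@tMax) else Inf)
  states <- if (!is.null(res$states)) {
    m <- res$states
    colnames(m) <- speciesNames(extended = TRUE)
    m
  } else {
    matrix(res$finalState, nrow = 1,
           dimnames = list(NULL, speciesNames(extended = TRUE)))
  }
  new("Trajectory",
      time = if (!is.null(res$time)) res$time else res$endTime,
      states = states, unitSystem = "molecules",
      metadata = list(tCross = res$tCross, nUKAtCross = res$nUKAtCross,
                      tAllAttached = res$tAllAttached,
                      endTime = res$endTime, finalState = res$finalState,
                      seed = protocol@seed, protocol = protocol))
}

#' Classify the outcome of a stochastic trajectory
#'
#' First-passage classification at the anaphase-entry threshold on
#' APC/C-Cdc20 (80 molecules): *adapted* if the first up-crossing happens
#' with at least one unattached kinetochore, *exited* if it happens after
#' the last attachment, *arrested* if there is no crossing within the
#' horizon.
#'
#' @param traj a [Trajectory-class] from [ssaRun()].
#' @param params the parameter set (for the threshold).
#' @return an [OutcomeRecord-class].
#' @export
classifyOutcome <- function(traj, params = checkpointParams("molecules")) {
  md <- traj@metadata
  if (is.null(md$tCross)) {
    if (!"nUK" %in% colnames(traj@states))
      stop("trajectory lacks an nUK channel")
    ac <- traj@states[, "AC"]
    idx <- which(ac >= acThreshold(params))[1]
    md$tCross <- if (is.na(idx)) NA_real_ else traj@time[idx]
    md$nUKAtCross <- if (is.na(idx)) NA_real_ else traj@states[idx, "nUK"]
    md$tAllAttached <- NA_real_
  }
  cl <- if (is.na(md$tCross)) "arrested"
        else if (md$nUKAtCross > 0) "adapted" else "exited"
  new("OutcomeRecord", seed = as.integer(md$seed %||% NA),
      tCross = as.numeric(md$tCross),
      nUKAtCross = as.numeric(md$nUKAtCross),
      tAllAttached = as.numeric(md$tAllAttached %||% NA),
      classification = cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a seeded ensemble of stochastic protocols
#'
#' `n` independent runs with seeds `seed0, seed0+1, ...`; deterministic
#' given `(seed0, n)`.
#'
#' @param protocol a [ProtocolSpec-class] (its own seed is ignored).
#' @param params molecule-unit parameters.
#' @param n number of runs.
#' @param seed0 base seed.
#' @return an [EnsembleSummary-class].
#' @export
runEnsemble <- function(protocol, params = checkpointParams("molecules"),
                        n = 100, seed0 = 1L) {
  stopifnot(n >= 1)
  rows <- lapply(seq_len(n) - 1L, function(i) {
    pr <- protocol
    pr@seed <- as.integer(seed0 + i)
    oc <- classifyOutcome(ssaRun(pr, params, recordDt = 0,
                                 stopAtCross = FALSE), params)
    data.frame(seed = oc@seed, tCross = oc@tCross,
               nUKAtCross = oc@nUKAtCross, tAllAttached = oc@tAllAttached,
               classification = oc@classification)
  })
  out <- do.call(rbind, rows)
  fr <- c(adapted = mean(out$classification == "adapted"),
          exited = mean(out$classification == "exited"),
          arrested = mean(out$classification == "arrested"))
  new("EnsembleSummary", outcomes = out, n = as.integer(n), fractions = fr,
      protocol = protocol, seed0 = as.integer(seed0))
}

#' @describeIn runEnsemble outcome table accessor.
#' @param summary an `EnsembleSummary`.
#' @export
outcomes <- function(summary) summary@outcomes

#' @describeIn runEnsemble classification fractions accessor.
#' @export
outcomeFractions <- function(summary) summary@fractions

#' Empirical distribution of adaptation (first-passage) times
#'
#' The cumulative distribution of threshold-crossing times, a
#' maximum-likelihood exponential fit after an optional delay, and the
#' coefficient of variation as a memorylessness diagnostic (CV of 1 is
#' the exponential signature; simulated arrests have no delay because
#' APC/C-Cdc20 is already formed at t = 0).
#'
#' @param summary an [EnsembleSummary-class].
#' @param delay fixed delay subtracted before the exponential fit
#'   (default 0).
#' @param minEvents minimal number of crossings required.
#' @return list: `times` (sorted), `cdf` (function), `rate` (ML
#'   exponential rate on times - delay), `delay`, `cv`, and
#'   `exponentialLike` (`FALSE` for degenerate/constant samples).
#' @export
adaptationTimeDistribution <- function(summary, delay = 0, minEvents = 20) {
  tt <- summary@outcomes$tCross
  tt <- sort(tt[!is.na(tt)])
  if (length(tt) < minEvents)
    stop("too few threshold crossings (", length(tt), ") for a fit")
  shifted <- pmax(tt - delay, 0)
  cv <- stats::sd(tt) / mean(tt)
  list(times = tt, cdf = stats::ecdf(tt),
       rate = 1 / mean(shifted), delay = delay, cv = cv,
       exponentialLike = is.finite(cv) && cv > 0.5)
}

#' Compare adapters with checkpoint-satisfying exiters
#'
#' Pearson correlation between crossing time and the number of unattached
#' kinetochores at crossing among adapters (early adapters escape with
#' many unattached kinetochores, so the correlation is negative in wild
#' type), plus the two timing distributions and a rank test of whether
#' adapters cross earlier.
#'
#' @param summary an [EnsembleSummary-class] from a washout protocol.
#' @return list: `R`, `p` (Pearson, among adapters), `adapterTimes`,
#'   `exiterTimes`, `wilcoxP` (one-sided, adapters earlier), and `flag`
#'   describing a missing class if one is empty.
#' @export
adaptersVsExiters <- function(summary) {
  oc <- summary@outcomes
  ad <- oc[oc$classification == "adapted", ]
  ex <- oc[oc$classification == "exited", ]
  res <- list(adapterTimes = ad$tCross, exiterTimes = ex$tCross,
              R = NA_real_, p = NA_real_, wilcoxP = NA_real_, flag = NULL)
  if (nrow(ad) == 0L || nrow(ex) == 0L) {
    res$flag <- paste("empty class:",
                      if (nrow(ad) == 0L) "adapted" else "exited")
    return(res)
  }
  if (nrow(ad) >= 3L && stats::sd(ad$nUKAtCross) > 0) {
    ct <- stats::cor.test(ad$tCross, ad$nUKAtCross, method = "pearson")
    res$R <- unname(ct$estimate)
    res$p <- ct$p.value
  }
  res$wilcoxP <- stats::wilcox.test(ad$tCross, ex$tCross,
                                    alternative = "less",
                                    exact = FALSE)$p.value
  res
}
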