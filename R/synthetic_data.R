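## Ground-truth-labeled synthetic observables: single-cell traces and
## cohorts emulating the time-lapse readouts (10-min frames, Clb2
## rise/plateau/fall, Mad2 localization index), toy spot images for the
## localization operators, and the mapping from stochastic trajectories
## to experiment-like traces.

#' Cohort specification constructor
#'
#' Defaults emulate the wild-type washout cohort: 60% adapting cells,
#' arrest lengths delay + Exp(rate) with a 100-min delay and a 150-min
#' mean, full Clb2 decay at 0.05/min (partial decay is fixed at
#' 0.005/min, below the 0.01 cutoff), Mad2 delocalizing 30 min before
#' the Clb2 fall in exiting cells and 30 min after it in adapting cells,
#' 2% Gaussian noise, 10-min frames.
#'
#' @param n number of cells.
#' @param fractionAdapting,fractionPartial,fractionArrested class mix;
#'   the remainder exits.
#' @param delay,rate shifted-exponential arrest-length law (min, 1/min).
#' @param clb2DecayRate Clb2 fall rate for full degraders (1/min).
#' @param mad2Lead Mad2 delocalization lead/lag vs the Clb2 fall (min).
#' @param noise Gaussian noise s.d. as a fraction of the Clb2 plateau.
#' @param frameSpacing frame interval (min).
#' @param seed base seed; cell i uses seed + i.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(n = 100, fractionAdapting = 0.6,
                       fractionPartial = 0, fractionArrested = 0,
                       delay = 100, rate = 1 / 150, clb2DecayRate = 0.05,
                       mad2Lead = 30, noise = 0.02, frameSpacing = 10,
                       seed = 1L) {
  new("CohortSpec", n = as.integer(n), fractionAdapting = fractionAdapting,
      fractionPartial = fractionPartial, fractionArrested = fractionArrested,
      delay = delay, rate = rate, clb2DecayRate = clb2DecayRate,
      mad2Lead = mad2Lead, noise = noise, frameSpacing = frameSpacing,
      seed = as.integer(seed))
}

.CLB2_PLATEAU <- 100
.MAD2_BASE <- 1
.MAD2_HIGH <- 3
.BUDDING <- 20
.RISE_END <- 60

#' Generate one labeled synthetic cell trace
#'
#' Clb2 rises after budding, holds a plateau for a random arrest length
#' (delay + exponential), then falls exponentially (fast for full
#' degraders, at 0.005/min for `"partial"`, never for `"arrested"`).
#' The Mad2 localization index sits at a G1 baseline, rises during the
#' arrest, and returns to baseline `mad2Lead` minutes before the Clb2
#' fall for `"exited"` cells and after it for `"adapted"` cells.
#'
#' @param label `"adapted"`, `"exited"`, `"partial"` or `"arrested"`.
#' @param spec a [CohortSpec-class].
#' @param seed integer seed for this cell.
#' @return a [CellTrace-class] carrying the label as ground truth.
#' @export
makeTrace <- function(label = c("adapted", "exited", "partial", "arrested"),
                      spec = cohortSpec(), seed = 1L) {
  label <- match.arg(label)
  set.seed(seed)
  dt <- spec@frameSpacing
  arrest <- spec@delay + stats::rexp(1, spec@rate)
  tFall <- round((.RISE_END + arrest) / dt) * dt
  tEnd <- ceiling((tFall + max(120, 3 * spec@mad2Lead)) / dt) * dt
  tt <- seq(0, tEnd, by = dt)
  rise <- pmin(pmax((tt - .BUDDING) / (.RISE_END - .BUDDING), 0), 1)
  clb2 <- .CLB2_PLATEAU * rise
  fallRate <- switch(label, partial = 0.005, spec@clb2DecayRate)
  if (label != "arrested") {
    post <- tt > tFall
    clb2[post] <- .CLB2_PLATEAU * exp(-fallRate * (tt[post] - tFall))
  }
  tDeloc <- switch(label,
    exited = tFall - spec@mad2Lead,
    adapted = tFall + spec@mad2Lead,
    Inf)                                  # partial/arrested stay localized
  mad2 <- ifelse(tt <= .BUDDING, .MAD2_BASE,
                 ifelse(tt <= tDeloc, .MAD2_HIGH, .MAD2_BASE))
  if (spec@noise > 0) {
    clb2 <- clb2 + stats::rnorm(length(tt), 0,
                                spec@noise * .CLB2_PLATEAU)
    mad2 <- mad2 + stats::rnorm(length(tt), 0, spec@noise * .MAD2_HIGH)
  }
  cellTrace(tt, clb2, mad2, buddingTime = .BUDDING, label = label,
            meta = list(tFall = tFall, arrest = arrest, seed = seed))
}

#' Generate a labeled cohort of synthetic traces
#'
#' @param spec a [CohortSpec-class].
#' @return list of [CellTrace-class]; reproducible given `spec@seed`.
#' @export
makeCohort <- function(spec = cohortSpec()) {
  if (spec@n == 0L) return(list())
  set.seed(spec@seed)
  u <- stats::runif(spec@n)
  cut1 <- spec@fractionAdapting
  cut2 <- cut1 + spec@fractionPartial
  cut3 <- cut2 + spec@fractionArrested
  labels <- ifelse(u < cut1, "adapted",
            ifelse(u < cut2, "partial",
            ifelse(u < cut3, "arrested", "exited")))
  lapply(seq_len(spec@n), function(i)
    makeTrace(labels[i], spec, seed = spec@seed + i))
}

#' Generate a toy kinetochore spot image
#'
#' A small intensity grid with Gaussian background noise and, optionally,
#' one Gaussian spot (sigma = 1 px) at the center, plus a full-frame
#' segmentation mask — fixtures for the localization-index and
#' kinetochore-signal operators.
#'
#' @param size image side (pixels, >= 5).
#' @param spot `"present"` or `"absent"`.
#' @param amplitude peak amplitude of the spot.
#' @param background constant background level.
#' @param noise Gaussian noise s.d.
#' @param seed integer seed.
#' @param sigma spot width (pixels).
#' @return list: `image`, `mask`, `truth` (list with spot presence,
#'   center and amplitude).
#' @export
makeSpotImage <- function(size = 15, spot = c("present", "absent"),
                          amplitude = 50, background = 10, noise = 1,
                          seed = 1L, sigma = 1) {
  spot <- match.arg(spot)
  if (size < 5) stop("size must be at least 5 pixels")
  set.seed(seed)
  img <- matrix(background + stats::rnorm(size^2, 0, noise), size, size)
  ctr <- c((size + 1) %/% 2, (size + 1) %/% 2)
  if (spot == "present" && amplitude > 0) {
    d2 <- outer((seq_len(size) - ctr[1])^2, (seq_len(size) - ctr[2])^2, `+`)
    img <- img + amplitude * exp(-d2 / (2 * sigma^2))
  }
  list(image = img, mask = matrix(TRUE, size, size),
       truth = list(spot = spot == "present", center = ctr,
                    amplitude = amplitude))
}

#' Map a stochastic trajectory to experiment-like observables
#'
#' Builds the single-cell trace a microscope would record for the
#' simulated cell: a G1 prefix and Clb2 rise, a Clb2 plateau until the
#' first APC/C-Cdc20 threshold crossing followed by exponential decay,
#' and a Mad2 localization-index proxy that is a saturating function of
#' the current number of unattached kinetochores (baseline at nUK = 0).
#' Mad2 localization is the checkpoint-signaling readout and Clb2
#' degradation the APC/C-Cdc20 activity readout, so the trace carries
#' the trajectory's own outcome classification as ground truth.
#'
#' @param traj a [Trajectory-class] from [ssaRun()] recorded on a grid.
#' @param params parameter set (threshold).
#' @param decayRate Clb2 decay rate after APC/C activation (1/min).
#' @param noise Gaussian noise fraction (0 for a noise-free readout).
#' @param frameSpacing frame interval (min).
#' @param seed seed for the readout noise.
#' @return a [CellTrace-class].
#' @export
modelToObservables <- function(traj, params = checkpointParams("molecules"),
                               decayRate = 0.05, noise = 0,
                               frameSpacing = 10, seed = 1L) {
  if (!all(c("AC", "nUK") %in% colnames(traj@states)))
    stop("trajectory must record AC and nUK channels")
  md <- traj@metadata
  oc <- classifyOutcome(traj, params)
  label <- if (oc@classification == "arrested") "arrested"
           else oc@classification
  tCross <- oc@tCross
  offset <- .RISE_END
  endSSA <- max(traj@time)
  tFall <- if (is.na(tCross)) Inf
           else ceiling((offset + tCross) / frameSpacing) * frameSpacing
  tEnd <- ceiling((offset + endSSA + 60) / frameSpacing) * frameSpacing
  tt <- seq(0, tEnd, by = frameSpacing)
  rise <- pmin(pmax((tt - .BUDDING) / (.RISE_END - .BUDDING), 0), 1)
  clb2 <- .CLB2_PLATEAU * rise
  post <- tt > tFall
  clb2[post] <- .CLB2_PLATEAU * exp(-decayRate * (tt[post] - tFall))
  nukAt <- function(tObs) {
    tS <- pmin(pmax(tObs - offset, 0), endSSA)
    idx <- findInterval(tS, traj@time)
    traj@states[pmax(idx, 1), "nUK"]
  }
  nuk <- nukAt(tt)
  ## the localization readout at the degradation frame reflects the state
  ## at APC/C activation (the crossing may fall between frames)
  if (is.finite(tFall) && !is.na(oc@nUKAtCross))
    nuk[which(tt == tFall)] <- oc@nUKAtCross
  mad2 <- ifelse(tt <= .BUDDING, .MAD2_BASE,
                 .MAD2_BASE + (.MAD2_HIGH - .MAD2_BASE) * nuk / (2 + nuk))
  if (noise > 0) {
    set.seed(seed)
    clb2 <- clb2 + stats::rnorm(length(tt), 0, noise * .CLB2_PLATEAU)
    mad2 <- mad2 + stats::rnorm(length(tt), 0, noise * .MAD2_HIGH)
  }
  cellTrace(tt, clb2, mad2, buddingTime = .BUDDING, label = label,
            meta = list(tCross = tCross, nUKAtCross = oc@nUKAtCross,
                        offset = offset))
}
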