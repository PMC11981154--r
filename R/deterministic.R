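## Deterministic engine: stiff ODE integration, steady states by
## integrate-then-polish (damped Newton), saddle-node location by
## bisection on existence of the checkpoint-ON fixed point, bifurcation
## scans, and the Mps1-pulse hysteresis experiment.

.rhs_desolve <- function(t, y, parms) {
  nUK <- if (is.function(parms$nUK)) parms$nUK(t) else parms$nUK
  list(odeRHS(stats::setNames(y, .SPECIES), parms$params, nUK,
              dutyCycle = parms$dutyCycle))
}

#' Integrate the deterministic model
#'
#' Stiff-safe integration (deSolve, lsoda) of the mean-field equations
#' with nUK following a piecewise-constant schedule. The conserved APC and
#' Mad moieties are preserved structurally; integration tolerances keep
#' relative drift below 1e-6 over 10^4 minutes.
#'
#' @param state0 named species vector (initial condition).
#' @param params a [CheckpointParams-class].
#' @param tEnd horizon (min).
#' @param nUK a single kinetochore count, or a data.frame `(time, nUK)` of
#'   left-closed piecewise-constant segments starting at time 0.
#' @param dt output sampling interval (min).
#' @param dutyCycle synthesis duty-cycle multiplier (see [odeRHS()]).
#' @param paramsSchedule optional data.frame-free alternative: a list of
#'   `list(from, to, params)` segments overriding `params` in time windows
#'   (used by the pulse protocol).
#' @return a [Trajectory-class].
#' @export
integrateModel <- function(state0, params, tEnd, nUK = 10, dt = 1,
                           dutyCycle = 1, paramsSchedule = NULL) {
  stopifnot(tEnd > 0)
  state0 <- state0[.SPECIES]
  nUKfun <- if (is.data.frame(nUK)) {
    stepfun(nUK$time[-1], nUK$nUK)
  } else {
    force(nUK); function(t) nUK
  }
  segs <- if (is.null(paramsSchedule)) {
    list(list(from = 0, to = tEnd, params = params))
  } else paramsSchedule
  times_all <- numeric(0); states_all <- NULL
  y <- state0
  for (sg in segs) {
    tt <- unique(c(seq(sg$from, sg$to, by = dt), sg$to))
    out <- deSolve::ode(y, tt, .rhs_desolve,
                        parms = list(params = sg$params, nUK = nUKfun,
                                     dutyCycle = dutyCycle),
                        method = "lsoda", rtol = 1e-10, atol = 1e-10,
                        maxsteps = 5e5)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integration failed at t = %.3f min",
                   out[nrow(out), 1]))
    m <- out[, -1, drop = FALSE]
    colnames(m) <- .SPECIES
    keep <- if (length(times_all)) -1L else TRUE   # avoid duplicate joins
    times_all <- c(times_all, out[keep, 1])
    states_all <- rbind(states_all, m[keep, , drop = FALSE])
    y <- m[nrow(m), ]
  }
  nUKcol <- vapply(times_all, nUKfun, 0)
  new("Trajectory", time = times_all,
      states = cbind(states_all, nUK = nUKcol),
      unitSystem = params@unitSystem,
      metadata = list(dutyCycle = dutyCycle))
}

#' @describeIn integrateModel final state of a trajectory.
#' @param traj a [Trajectory-class].
#' @export
finalState <- function(traj) traj@states[nrow(traj@states), ]

#' @describeIn integrateModel trajectory as a tidy data.frame
#'   (time, variable, value).
#' @export
asTidy <- function(traj) {
  df <- data.frame(time = traj@time, traj@states, check.names = FALSE)
  stats::reshape(df, direction = "long",
                 varying = colnames(traj@states),
                 v.names = "value", timevar = "variable",
                 times = colnames(traj@states),
                 idvar = "time")[, c("time", "variable", "value")]
}

.jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, length(f(x)))
  for (i in seq_len(n)) {
    h <- eps * max(abs(x[i]), 1)
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[i, ] <- (f(xp) - f(xm)) / (2 * h)
  }
  t(J)
}

## Reduced coordinates: the APC and Mad moieties are conserved, so the
## full 8-species Jacobian is singular along those two directions. Fixed
## points are refined in the 6 free coordinates with A and Madi
## eliminated through the totals.
.RED_VARS <- c("C", "AC", "Mada", "Mps1", "MC", "ACMC")

.expand_state <- function(z, totals) {
  z <- stats::setNames(z, .RED_VARS)
  c(C = z[["C"]], A = totals[["APC"]] - z[["AC"]] - z[["ACMC"]],
    AC = z[["AC"]], Mada = z[["Mada"]],
    Madi = totals[["Mad"]] - z[["Mada"]] - z[["MC"]] - z[["ACMC"]],
    Mps1 = z[["Mps1"]], MC = z[["MC"]], ACMC = z[["ACMC"]])
}

.reduced_f <- function(params, nUK, totals, dutyCycle = 1) {
  function(z) {
    x <- .expand_state(z, totals)
    odeRHS(x, params, nUK, dutyCycle = dutyCycle)[.RED_VARS]
  }
}

.newton_polish <- function(x0, f, tol, maxit = 100) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) return(list(x = x, ok = TRUE))
    J <- .jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, ok = FALSE))
    lam <- 1
    while (lam >= 1e-8) {                      # damping
      xn <- x + lam * step
      if (sum(f(xn)^2) < sum(fx^2)) break
      lam <- lam / 2
    }
    if (lam < 1e-8) return(list(x = x, ok = max(abs(f(x))) < tol))
    x <- x + lam * step
  }
  list(x = x, ok = max(abs(f(x))) < tol)
}

.settle <- function(state0, params, nUK, t = 20000, dutyCycle = 1) {
  out <- deSolve::ode(state0[.SPECIES], c(0, t), .rhs_desolve,
                      parms = list(params = params, nUK = nUK,
                                   dutyCycle = dutyCycle),
                      method = "bdf", rtol = 1e-8, atol = 1e-8,
                      maxsteps = 5e5)
  stats::setNames(out[nrow(out), -1], .SPECIES)
}

#' Find the fixed points of the deterministic model
#'
#' Multi-start search: long integrations seeded from the checkpoint-ON and
#' checkpoint-OFF reference states locate the stable branches, each
#' polished with a damped Newton iteration to a residual below
#' `tol` times the characteristic flux; the unstable middle state, when the
#' system is bistable, is found by bisecting the ON-OFF segment on basin
#' membership and polishing. Stability is read off the Jacobian spectrum.
#'
#' @param params a [CheckpointParams-class].
#' @param nUK kinetochore count (continuous bifurcation parameter).
#' @param madTotalFactor optional Mad-pool scaling applied to the seeds
#'   (the conserved total selects the branch system of an overexpression
#'   mutant).
#' @param tol relative residual tolerance (default 1e-8).
#' @param dutyCycle synthesis duty-cycle multiplier.
#' @return data.frame: one row per fixed point, species columns, a
#'   `stability` column (`"stable"`/`"unstable"`) and a `branch` label
#'   (`"ON"` low APC/C-Cdc20, `"OFF"` high, `"middle"`).
#' @export
findSteadyStates <- function(params, nUK, madTotalFactor = 1, tol = 1e-8,
                             dutyCycle = 1) {
  us <- params@unitSystem
  spec <- mutantSpec(madTotalFactor = madTotalFactor)
  seeds <- list(mutantState(referenceState("on", us), spec),
                mutantState(referenceState("off", us), spec))
  totals <- moietyTotals(seeds[[1]])
  f <- .reduced_f(params, nUK, totals, dutyCycle)
  flux0 <- max(abs(reactionRates(seeds[[1]], params, nUK = nUK)))
  atol <- tol * flux0
  fps <- list()
  for (sd in seeds) {
    st <- .settle(sd, params, nUK, dutyCycle = dutyCycle)
    pol <- .newton_polish(st[.RED_VARS], f, atol)
    if (pol$ok) fps <- c(fps, list(stats::setNames(pol$x, .RED_VARS)))
  }
  if (!length(fps)) stop("no steady state found from any start")
  dedup <- function(lst) {
    out <- list()
    for (x in lst) {
      dup <- any(vapply(out, function(y)
        max(abs(x - y)) < 1e-3 * max(1, max(abs(y))), TRUE))
      if (!dup) out <- c(out, list(x))
    }
    out
  }
  fps <- dedup(fps)
  ## bistable: locate the saddle between the branches by edge tracking —
  ## bisect the ON-OFF segment on basin membership, then repeatedly flow
  ## the bracket toward the saddle along the separatrix and re-bisect
  if (length(fps) == 2L) {
    ia <- which.min(vapply(fps, `[`, 0, "AC"))
    a <- .expand_state(fps[[ia]], totals)
    b <- .expand_state(fps[[3L - ia]], totals)
    onAC <- a[["AC"]]; offAC <- b[["AC"]]
    toON <- function(x) {
      st <- .settle(x, params, nUK, t = 5000, dutyCycle = dutyCycle)
      abs(st[["AC"]] - onAC) < abs(st[["AC"]] - offAC)
    }
    bisect <- function(xa, xb) {
      lo <- 0; hi <- 1
      for (i in 1:25) {
        mid <- (lo + hi) / 2
        if (toON(xa + mid * (xb - xa))) lo <- mid else hi <- mid
      }
      list(a = xa + lo * (xb - xa), b = xa + hi * (xb - xa))
    }
    br <- bisect(a, b)
    for (round in 1:6) {
      mid <- (br$a + br$b) / 2
      pol <- .newton_polish(mid[.RED_VARS], f, atol)
      if (pol$ok) break
      fa <- .settle(br$a, params, nUK, t = 150, dutyCycle = dutyCycle)
      fb <- .settle(br$b, params, nUK, t = 150, dutyCycle = dutyCycle)
      br <- bisect(fa, fb)
    }
    if (pol$ok) fps <- dedup(c(fps, list(stats::setNames(pol$x, .RED_VARS))))
  }
  rows <- lapply(fps, function(z) {
    ev <- eigen(.jacobian(f, z), only.values = TRUE)$values
    stab <- if (all(Re(ev) < 0)) "stable" else "unstable"
    data.frame(t(.expand_state(z, totals)), stability = stab)
  })
  df <- do.call(rbind, rows)
  df$branch <- "middle"
  onCut <- 50 / ifelse(us == "nM", MOL_PER_NM, 1)
  stab <- df$stability == "stable"
  df$branch[stab] <- ifelse(df$AC[stab] < onCut, "ON", "OFF")
  df[order(df$AC), , drop = FALSE]
}

.has_on_state <- function(params, nUK, madTotalFactor = 1) {
  us <- params@unitSystem
  sd <- mutantState(referenceState("on", us),
                    mutantSpec(madTotalFactor = madTotalFactor))
  st <- .settle(sd, params, nUK, t = 6000)
  ## ON branch = low APC/C-Cdc20 (below half the OFF level)
  st["AC"] < 50 / ifelse(us == "nM", MOL_PER_NM, 1)
}

#' Locate the saddle-node bifurcation
#'
#' Bisection on the existence of the checkpoint-ON fixed point: the left
#' knee nUK* below which a cell cannot sustain the arrest. The ON state
#' must exist at `nUKHi` and not at `nUKLo`.
#'
#' @param params a [CheckpointParams-class].
#' @param nUKLo,nUKHi initial bracket (kinetochores).
#' @param tol bracket width at termination (default 0.01 kinetochores;
#'   results are conventionally reported to one decimal).
#' @param madTotalFactor Mad-pool scaling of the branch system.
#' @param mutant optional [MutantSpec-class]; applied to both the
#'   parameters and the Mad pool (overrides `madTotalFactor`).
#' @return a [SaddleNodeResult-class].
#' @examples
#' \donttest{
#' locateSaddleNode(checkpointParams())           # wild type
#' }
#' @export
locateSaddleNode <- function(params, nUKLo = 0.05, nUKHi = 2, tol = 0.01,
                             madTotalFactor = 1, mutant = NULL) {
  if (!is.null(mutant)) {
    params <- applyMutant(params, mutant)
    madTotalFactor <- mutant@madTotalFactor
  } else {
    mutant <- mutantSpec(madTotalFactor = madTotalFactor)
  }
  if (.has_on_state(params, nUKLo, madTotalFactor))
    stop("ON state already exists at nUKLo; lower the bracket")
  if (!.has_on_state(params, nUKHi, madTotalFactor))
    stop("no ON state at nUKHi; raise the bracket")
  lo <- nUKLo; hi <- nUKHi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.has_on_state(params, mid, madTotalFactor)) hi <- mid else lo <- mid
  }
  new("SaddleNodeResult", nUKStar = (lo + hi) / 2, bracket = hi - lo,
      mutant = mutant)
}

#' @describeIn locateSaddleNode saddle position (kinetochores).
#' @param x a `SaddleNodeResult`.
#' @export
nUKStar <- function(x) x@nUKStar

#' Bifurcation scan over a grid of kinetochore counts
#'
#' @param params a [CheckpointParams-class].
#' @param nUKGrid sorted kinetochore counts.
#' @param madTotalFactor Mad-pool scaling.
#' @return a [SteadyStateBranch-class]; its `branches` data.frame is
#'   suitable for plotting APC/C-Cdc20 against nUK, and the ON-to-middle
#'   distance per grid point is the checkpoint-strength proxy.
#' @export
bifurcationScan <- function(params, nUKGrid, madTotalFactor = 1) {
  stopifnot(!is.unsorted(nUKGrid))
  rows <- lapply(nUKGrid, function(u) {
    df <- findSteadyStates(params, u, madTotalFactor = madTotalFactor)
    cbind(nUK = u, df)
  })
  new("SteadyStateBranch", branches = do.call(rbind, rows),
      unitSystem = params@unitSystem)
}

#' @describeIn bifurcationScan distance between the ON and the unstable
#'   middle state (in APC/C-Cdc20), per grid point where both exist —
#'   proportional to checkpoint strength.
#' @param scan a `SteadyStateBranch`.
#' @export
checkpointStrength <- function(scan) {
  b <- scan@branches
  sapply(split(b, b$nUK), function(d) {
    if (all(c("ON", "middle") %in% d$branch))
      d$AC[d$branch == "middle"] - d$AC[d$branch == "ON"]
    else NA_real_
  })
}

#' Mps1-overexpression pulse experiment
#'
#' Starting from the checkpoint-OFF state at a signal level inside the
#' bistable window (lack of tension in an anaphase arrest), Mps1 synthesis
#' is raised for a fixed window and then restored. The trajectory switches
#' into the checkpoint-ON basin during the pulse and, by bistability,
#' remains there after it: hysteresis.
#'
#' @param params a [CheckpointParams-class].
#' @param signalLevel nUK-equivalent signal (default 10).
#' @param pulse a [MutantSpec-class] with the synthesis factor and window
#'   (default 3x over 0-60 min).
#' @param tEnd horizon (min).
#' @return list with the [Trajectory-class] (`trajectory`) and the end
#'   label (`"ON"` or `"OFF"`).
#' @export
simulatePulse <- function(params, signalLevel = 10,
                          pulse = mutantSpec(mps1SynthesisFactor = 3,
                                             window = c(0, 60)),
                          tEnd = 600) {
  if (!.has_on_state(params, signalLevel))
    stop("signal level is below the saddle node: no ON state to be trapped in")
  w <- pmin(pmax(pulse@window, 0), tEnd)
  pp <- applyMutant(params, pulse, time = mean(w))
  segs <- list()
  if (w[1] > 0) segs <- c(segs, list(list(from = 0, to = w[1], params = params)))
  segs <- c(segs, list(list(from = w[1], to = w[2], params = pp)))
  if (w[2] < tEnd) segs <- c(segs, list(list(from = w[2], to = tEnd,
                                             params = params)))
  traj <- integrateModel(referenceState("off", params@unitSystem), params,
                         tEnd, nUK = signalLevel, paramsSchedule = segs)
  acEnd <- finalState(traj)[["AC"]]
  onLevel <- 50 / ifelse(params@unitSystem == "nM", MOL_PER_NM, 1)
  list(trajectory = traj, endState = if (acEnd < onLevel) "ON" else "OFF")
}
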