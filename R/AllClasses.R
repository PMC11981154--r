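#' @import methods
NULL

## Central S4 containers. Species are always ordered as in `speciesNames()`:
## C, A, AC, Mada, Madi, Mps1, MC, ACMC; the extended state appends the
## promoter occupancies (ponCDC20, ponX) and the unattached-kinetochore
## count nUK.

#' Parameter set of the checkpoint model
#'
#' Holds one internally consistent parameterization of the reaction network,
#' either in molecules/nucleus ("molecules", used by the stochastic engine)
#' or in nM ("nM", the deterministic reporting scale; related by the nuclear
#' volume conversion of 2.5 molecules per nM). All first-order rates are in
#' 1/min, bimolecular rates in 1/(unit x min), synthesis in unit/min.
#'
#' @slot values named numeric vector of rate and saturation constants.
#' @slot unitSystem `"molecules"` or `"nM"`.
#' @slot acThreshold anaphase-entry threshold on APC/C-Cdc20, in the active
#'   unit system (80 molecules, equivalently 32 nM).
#' @exportClass CheckpointParams
setClass("CheckpointParams",
  representation(values = "numeric", unitSystem = "character",
                 acThreshold = "numeric"))

setValidity("CheckpointParams", function(object) {
  need <- c("kdeg", "ksynCDC20", "kassMC", "kDMC", "kassAC", "kDAC",
            "kassACMC", "kDACMC", "kdegBG", "kact", "kinact", "ksynX",
            "kdegX", "kdegBGX", "katt", "kprime", "Jn", "J",
            "konCDC20", "koffCDC20", "konX", "koffX")
  msg <- character()
  if (!all(need %in% names(object@values)))
    msg <- c(msg, paste("missing parameters:",
                        paste(setdiff(need, names(object@values)), collapse = ", ")))
  else if (any(object@values[need] < 0))
    msg <- c(msg, "all rate and saturation constants must be >= 0")
  if (length(object@unitSystem) != 1L ||
      !object@unitSystem %in% c("molecules", "nM"))
    msg <- c(msg, "unitSystem must be 'molecules' or 'nM'")
  if (length(object@acThreshold) != 1L || object@acThreshold <= 0)
    msg <- c(msg, "acThreshold must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Mutant transform specification
#'
#' Multiplicative perturbations of the wild-type model: reduced APC/C-Cdc20
#' association (APC-A class mutants), an enlarged conserved Mad pool
#' (GAL1-MAD2 class), and transient Mps1 overexpression (synthesis factor
#' over a time window, as in the anaphase Mps1-pulse experiment).
#'
#' @slot kassACFactor scale on the APC/C-Cdc20 association rate (dissociation
#'   rate held fixed, so the dissociation constant rises as the factor falls).
#' @slot madTotalFactor scale on the conserved Mad moiety total; extra Mad
#'   enters the inactive pool.
#' @slot mps1SynthesisFactor scale on Mps1 synthesis.
#' @slot window numeric length-2 time window (min) over which the Mps1
#'   synthesis factor is active; `c(-Inf, Inf)` means always.
#' @exportClass MutantSpec
setClass("MutantSpec",
  representation(kassACFactor = "numeric", madTotalFactor = "numeric",
                 mps1SynthesisFactor = "numeric", window = "numeric"),
  prototype(kassACFactor = 1, madTotalFactor = 1, mps1SynthesisFactor = 1,
            window = c(-Inf, Inf)))

setValidity("MutantSpec", function(object) {
  msg <- character()
  for (s in c("kassACFactor", "madTotalFactor", "mps1SynthesisFactor"))
    if (length(slot(object, s)) != 1L || slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be c(start, end) with start < end")
  if (length(msg)) msg else TRUE
})

#' Reaction network of the checkpoint model
#'
#' The 22 elementary reactions driving both the deterministic and the
#' stochastic engine: promoter switching and bursty synthesis for Cdc20 and
#' Mps1, targeted and background degradation, Mad activation/inactivation,
#' MCC and APC/C-Cdc20 and APC/C-MCC assembly/disassembly, APC/C-MCC
#' turnover, and kinetochore attachment.
#'
#' @slot species character vector of state-variable names (8 molecular
#'   species + 2 promoters + nUK).
#' @slot stoich integer stoichiometry matrix, species x reactions.
#' @slot rateLaw character tag per reaction.
#' @slot reactions human-readable reaction strings.
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  representation(species = "character", stoich = "matrix",
                 rateLaw = "character", reactions = "character"))

setValidity("ReactionNetwork", function(object) {
  S <- object@stoich
  msg <- character()
  if (!identical(rownames(S), object@species))
    msg <- c(msg, "stoichiometry rows must match species")
  apc <- c(A = 1, AC = 1, ACMC = 1)
  mad <- c(Mada = 1, Madi = 1, MC = 1, ACMC = 1)
  for (nm in list(apc = apc, mad = mad)) TRUE
  if (any(colSums(S[names(apc), , drop = FALSE] * apc) != 0))
    msg <- c(msg, "a reaction violates APC moiety conservation")
  if (any(colSums(S[names(mad), , drop = FALSE] * mad) != 0))
    msg <- c(msg, "a reaction violates Mad moiety conservation")
  if (length(msg)) msg else TRUE
})

#' In-silico experiment protocol
#'
#' @slot mode `"arrest"` (fixed nUK), `"washout"` (first-order attachment
#'   from t = 0) or `"pulse"` (transient Mps1 overexpression).
#' @slot nUK0 initial number of unattached kinetochores.
#' @slot attachment logical; whether the attachment channel fires.
#' @slot mutant a [MutantSpec-class].
#' @slot tMax simulation horizon (min).
#' @slot init `"on"`, `"off"` or a named numeric custom state.
#' @slot seed integer seed for the run.
#' @exportClass ProtocolSpec
setClass("ProtocolSpec",
  representation(mode = "character", nUK0 = "numeric", attachment = "logical",
                 mutant = "MutantSpec", tMax = "numeric", init = "ANY",
                 seed = "integer"))

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("arrest", "washout", "pulse"))
    msg <- c(msg, "mode must be 'arrest', 'washout' or 'pulse'")
  if (object@nUK0 < 0 || object@nUK0 != round(object@nUK0))
    msg <- c(msg, "nUK0 must be a nonnegative integer")
  if (object@mode == "arrest" && object@attachment)
    msg <- c(msg, "fixed-nUK arrest must not fire the attachment reaction")
  if (object@mode == "washout" && !object@attachment)
    msg <- c(msg, "washout mode starts attachment at t = 0")
  if (object@tMax <= 0) msg <- c(msg, "tMax must be positive")
  if (length(msg)) msg else TRUE
})

#' Time-stamped model trajectory
#'
#' @slot time sampling times (min).
#' @slot states numeric matrix, one row per time point; columns are the
#'   species, plus `ponCDC20`, `ponX`, `nUK` for stochastic paths.
#' @slot unitSystem unit system of the state columns.
#' @slot metadata list (protocol, first-passage record, parameters digest).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(time = "numeric", states = "matrix", unitSystem = "character",
                 metadata = "list"))

#' Per-trajectory outcome of a stochastic protocol
#'
#' Classification follows the model's operational definitions: *adapted* =
#' APC/C-Cdc20 reached the activation threshold while at least one
#' kinetochore was still unattached; *exited* = threshold reached with all
#' kinetochores attached (checkpoint satisfied); *arrested* = no crossing
#' within the horizon.
#'
#' @slot seed integer run seed.
#' @slot tCross first threshold up-crossing time (min), `NA` if none.
#' @slot nUKAtCross unattached kinetochores at the crossing.
#' @slot tAllAttached time the last kinetochore attached (washout), `NA`.
#' @slot classification `"adapted"`, `"exited"` or `"arrested"`.
#' @exportClass OutcomeRecord
setClass("OutcomeRecord",
  representation(seed = "integer", tCross = "numeric", nUKAtCross = "numeric",
                 tAllAttached = "numeric", classification = "character"))

setValidity("OutcomeRecord", function(object) {
  cl <- object@classification
  ok <- switch(cl,
    adapted  = !is.na(object@tCross) && object@nUKAtCross > 0,
    exited   = !is.na(object@tCross) && object@nUKAtCross == 0,
    arrested = is.na(object@tCross),
    FALSE)
  if (ok) TRUE else "classification inconsistent with tCross/nUKAtCross"
})

#' Summary of an ensemble of stochastic runs
#'
#' @slot outcomes data.frame with one row per run (seed, tCross, nUKAtCross,
#'   tAllAttached, classification).
#' @slot n number of runs.
#' @slot fractions named fractions (adapted, exited, arrested); sum to 1.
#' @slot protocol the [ProtocolSpec-class] used.
#' @slot seed0 base seed; run i used seed0 + i - 1.
#' @exportClass EnsembleSummary
setClass("EnsembleSummary",
  representation(outcomes = "data.frame", n = "integer", fractions = "numeric",
                 protocol = "ProtocolSpec", seed0 = "integer"))

setValidity("EnsembleSummary", function(object) {
  if (abs(sum(object@fractions) - 1) > 1e-9) "fractions must sum to 1" else TRUE
})

#' Steady-state branches over a grid of unattached-kinetochore counts
#'
#' @slot branches data.frame: nUK, one column per species, `stability`
#'   (stable/unstable) and `branch` (ON/OFF/middle).
#' @slot unitSystem unit system of the species columns.
#' @exportClass SteadyStateBranch
setClass("SteadyStateBranch",
  representation(branches = "data.frame", unitSystem = "character"))

#' Location of the saddle-node bifurcation
#'
#' @slot nUKStar kinetochore count where the checkpoint-ON state is
#'   created/destroyed (the left knee of the bistable region).
#' @slot bracket final bisection bracket (resolution).
#' @slot mutant the [MutantSpec-class] the scan was run under.
#' @exportClass SaddleNodeResult
setClass("SaddleNodeResult",
  representation(nUKStar = "numeric", bracket = "numeric",
                 mutant = "MutantSpec"))

#' Single-cell observable trace
#'
#' A sampled time-lapse readout: mean Clb2 fluorescence (mitotic cyclin,
#' APC/C-Cdc20 activity reporter) and the Mad2 localization index
#' (checkpoint-engagement reporter), on a regular frame grid.
#'
#' @slot time frame times (min), strictly increasing.
#' @slot clb2 mean Clb2 fluorescence per frame (arbitrary units).
#' @slot mad2Index Mad2 localization index per frame.
#' @slot buddingTime time of first budding (min).
#' @slot label optional ground-truth label (`"adapted"`, `"exited"`,
#'   `"partial"`, `"arrested"`, or `NA`).
#' @slot meta list of generator/provenance metadata.
#' @exportClass CellTrace
setClass("CellTrace",
  representation(time = "numeric", clb2 = "numeric", mad2Index = "numeric",
                 buddingTime = "numeric", label = "character", meta = "list"),
  prototype(label = NA_character_, meta = list()))

setValidity("CellTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@clb2) ||
      length(object@time) != length(object@mad2Index))
    msg <- c(msg, "time, clb2 and mad2Index must have equal length")
  if (any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (!all(is.finite(object@clb2)) || !all(is.finite(object@mad2Index)))
    msg <- c(msg, "signals must be finite")
  if (length(msg)) msg else TRUE
})

#' Synthetic-cohort specification
#'
#' Defines the statistical structure of a generated cohort of single-cell
#' traces: class mix, the shifted-exponential law of arrest lengths, Clb2
#' decay kinetics, the Mad2 delocalization lead/lag that distinguishes
#' checkpoint satisfaction from adaptation, and the imaging noise level.
#'
#' @slot n number of cells.
#' @slot fractionAdapting,fractionPartial,fractionArrested class fractions;
#'   the remainder exits by satisfying the checkpoint.
#' @slot delay,rate arrest-length law: delay + Exp(rate) minutes.
#' @slot clb2DecayRate exponential Clb2 fall rate (1/min) for full degraders.
#' @slot mad2Lead minutes by which Mad2 delocalizes before the Clb2 fall in
#'   exiting cells (it delocalizes after the fall in adapting cells).
#' @slot noise Gaussian noise s.d. as a fraction of the Clb2 plateau.
#' @slot frameSpacing frame interval (min).
#' @slot seed base seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(n = "integer", fractionAdapting = "numeric",
                 fractionPartial = "numeric", fractionArrested = "numeric",
                 delay = "numeric", rate = "numeric", clb2DecayRate = "numeric",
                 mad2Lead = "numeric", noise = "numeric",
                 frameSpacing = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  fr <- c(object@fractionAdapting, object@fractionPartial,
          object@fractionArrested)
  if (any(fr < 0) || sum(fr) > 1)
    msg <- c(msg, "class fractions must be nonnegative and sum to <= 1")
  if (object@rate <= 0 || object@clb2DecayRate <= 0)
    msg <- c(msg, "rates must be positive")
  if (object@frameSpacing <= 0) msg <- c(msg, "frameSpacing must be positive")
  if (length(msg)) msg else TRUE
})

#' Trace/image analysis configuration
#'
#' @slot logKernel the fixed 3x3 Laplacian-of-Gaussian kernel.
#' @slot thresholdFactor localization threshold as a multiple of the G1
#'   calibration maximum (default 1.10).
#' @slot g1Window length of the G1 calibration window (min, default 20).
#' @slot kinetochoreWindow side of the square kinetochore mask (pixels).
#' @slot sgWindow,sgOrder Savitzky-Golay smoothing window (frames) and
#'   polynomial order.
#' @slot ratePoints number of frames used for the degradation-rate fit.
#' @slot partialRateCutoff rate (1/min) below which degradation is partial.
#' @slot partialFraction minimal fraction of Clb2 degraded within the
#'   horizon for full degradation.
#' @slot partialHorizon horizon for the fraction rule (min).
#' @slot fallK consecutive lower smoothed points required after a local
#'   maximum to call the onset of degradation.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(logKernel = "matrix", thresholdFactor = "numeric",
                 g1Window = "numeric", kinetochoreWindow = "integer",
                 sgWindow = "integer", sgOrder = "integer",
                 ratePoints = "integer", partialRateCutoff = "numeric",
                 partialFraction = "numeric", partialHorizon = "numeric",
                 fallK = "integer"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!identical(dim(object@logKernel), c(3L, 3L)))
    msg <- c(msg, "logKernel must be 3x3")
  if (object@kinetochoreWindow < 1L || object@sgWindow < 3L ||
      object@sgOrder < 1L || object@ratePoints < 2L || object@fallK < 1L)
    msg <- c(msg, "window sizes and orders must be positive")
  if (object@sgOrder >= object@sgWindow)
    msg <- c(msg, "sgOrder must be smaller than sgWindow")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "CheckpointParams", function(object) {
  cat("CheckpointParams [", object@unitSystem, "]: ",
      length(object@values), " constants; AC threshold ",
      object@acThreshold, "\n", sep = "")
})

setMethod("show", "MutantSpec", function(object) {
  cat(sprintf(
    "MutantSpec: kassAC x%.3g, Mad total x%.3g, Mps1 synthesis x%.3g",
    object@kassACFactor, object@madTotalFactor, object@mps1SynthesisFactor))
  if (is.finite(object@window[1]) || is.finite(object@window[2]))
    cat(sprintf(" over [%g, %g] min", object@window[1], object@window[2]))
  cat("\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory [", object@unitSystem, "]: ", length(object@time),
      " time points over [", min(object@time), ", ", max(object@time),
      "] min; columns: ", paste(colnames(object@states), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "EnsembleSummary", function(object) {
  cat("EnsembleSummary: ", object@n, " runs (",
      paste(sprintf("%s %.0f%%", names(object@fractions),
                    100 * object@fractions), collapse = ", "),
      ")\n", sep = "")
})

setMethod("show", "SaddleNodeResult", function(object) {
  cat(sprintf("Saddle-node at nUK* = %.2f (bracket %.3g)\n",
              object@nUKStar, object@bracket))
})

setMethod("show", "CellTrace", function(object) {
  cat("CellTrace: ", length(object@time), " frames, budding at t = ",
      object@buddingTime, if (!is.na(object@label))
        paste0(", label '", object@label, "'") else "", "\n", sep = "")
})
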