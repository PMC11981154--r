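## Model core: parameter sets, the reaction network, rate laws, mutants.
##
## The authoritative parameterization is the molecule-per-nucleus column;
## nM values follow from the nuclear volume bookkeeping 40 nM == 100
## molecules (2.5 molecules per nM, ~4.15 fL). Concentration-like
## quantities divide by 2.5, bimolecular rate constants multiply by 2.5,
## zero-order synthesis divides by 2.5, first-order rates are unchanged.

MOL_PER_NM <- 2.5

.PARAMS_MOL <- c(
  kdeg = 1.3, ksynCDC20 = 42, kassMC = 2.2e-2, kDMC = 1.4,
  kassAC = 1.1e-1, kDAC = 8.5, kassACMC = 5.8e-1, kDACMC = 1.1,
  kdegBG = 3.8e-2, kact = 2.4e-2, kinact = 6.7e-3, ksynX = 11,
  kdegX = 2.4e-2, kdegBGX = 6.2e-2, katt = 3.0e-2, kprime = 170,
  Jn = 0.4, J = 2.1, konCDC20 = 1.0, koffCDC20 = 0.1, konX = 1.0,
  koffX = 0.1)

## The deterministic (nM) column of the original tabulation, kept verbatim for side-by-side
## export. Its bimolecular constants do not balance the nM steady states
## (see the methods vignette); the engines never use it.
.PARAMS_NM_TABULATED <- c(
  kdeg = 1.3, ksynCDC20 = 17, kassMC = 8.8e-3, kDMC = 0.56,
  kassAC = 4.4e-2, kDAC = 3.4, kassACMC = 2.3e-1, kDACMC = 0.44,
  kdegBG = 3.8e-2, kact = 2.4e-2, kinact = 2.7e-3, ksynX = 4.4,
  kdegX = 9.6e-3, kdegBGX = 6.2e-2, katt = 3.0e-2, kprime = 170,
  Jn = 0.4, J = 0.84, konCDC20 = NA, koffCDC20 = NA, konX = NA, koffX = NA)

.SPECIES <- c("C", "A", "AC", "Mada", "Madi", "Mps1", "MC", "ACMC")
.STATE_VARS <- c(.SPECIES, "ponCDC20", "ponX", "nUK")

.ON_MOL <- c(C = 13, A = 45, AC = 25, Mada = 140, Madi = 2, Mps1 = 17,
             MC = 4, ACMC = 29)
.OFF_MOL <- c(C = 440, A = 2, AC = 82, Mada = 2, Madi = 156, Mps1 = 6,
              MC = 0, ACMC = 16)

#' Species names of the checkpoint model
#'
#' @param extended if `TRUE`, include the promoter occupancies and `nUK`.
#' @return character vector of state-variable names.
#' @export
speciesNames <- function(extended = FALSE)
  if (extended) .STATE_VARS else .SPECIES

#' Wild-type parameter set
#'
#' Returns the wild-type constants in the requested unit system. The
#' molecule column is the primary set; the nM set is its exact nuclear
#' volume conversion (2.5 molecules per nM), so both describe identical
#' dynamics. The anaphase-entry threshold on APC/C-Cdc20 is 80 molecules
#' (32 nM).
#'
#' @param unitSystem `"molecules"` (default, stochastic engine) or `"nM"`.
#' @return a [CheckpointParams-class] object.
#' @examples
#' p <- checkpointParams()
#' paramValues(p)[["kassAC"]]
#' @export
checkpointParams <- function(unitSystem = c("molecules", "nM")) {
  unitSystem <- match.arg(unitSystem)
  v <- .PARAMS_MOL
  thr <- 80
  if (unitSystem == "nM") {
    conc <- c("kDMC", "kDAC", "kDACMC", "J")
    ## kinact is first-order in the saturating inactivation law
    ## kinact * Mada^2 / (J + Mada) and does not volume-convert
    bimol <- c("kassMC", "kassAC", "kassACMC", "kdegX")
    synth <- c("ksynCDC20", "ksynX")
    v[conc] <- v[conc] / MOL_PER_NM
    v[bimol] <- v[bimol] * MOL_PER_NM
    v[synth] <- v[synth] / MOL_PER_NM
    thr <- thr / MOL_PER_NM
  }
  new("CheckpointParams", values = v, unitSystem = unitSystem,
      acThreshold = thr)
}

#' @describeIn checkpointParams named parameter vector.
#' @param object,params a `CheckpointParams` object.
#' @export
paramValues <- function(object) object@values

#' @describeIn checkpointParams active unit system.
#' @export
unitSystem <- function(object) object@unitSystem

#' @describeIn checkpointParams anaphase-entry threshold on APC/C-Cdc20.
#' @export
acThreshold <- function(object) object@acThreshold

#' @describeIn checkpointParams dissociation rates (1/min) derived from the
#'   dissociation constants, `kdiss = KD * kass`.
#' @export
derivedRates <- function(params) {
  v <- params@values
  c(kdissMC = unname(v["kDMC"] * v["kassMC"]),
    kdissAC = unname(v["kDAC"] * v["kassAC"]),
    kdissACMC = unname(v["kDACMC"] * v["kassACMC"]))
}

#' Tabulated parameter columns
#'
#' Both tabulated parameter columns side by side: the molecule column that
#' the engines use, and the as-tabulated deterministic nM column together
#' with the volume-consistent nM conversion actually used for nM reporting.
#'
#' @return data.frame with one row per constant.
#' @export
paramTable <- function() {
  nm <- checkpointParams("nM")@values
  data.frame(parameter = names(.PARAMS_MOL),
             molecules = unname(.PARAMS_MOL),
             nM_tabulated = unname(.PARAMS_NM_TABULATED[names(.PARAMS_MOL)]),
             nM_volume_consistent = unname(nm[names(.PARAMS_MOL)]),
             row.names = NULL)
}

#' Reference states of the arrested and released checkpoint
#'
#' The checkpoint-ON (arrest) and checkpoint-OFF initial conditions, which
#' are also, to tabulated precision, the two stable fixed points of the model
#' at ten unattached kinetochores.
#'
#' @param branch `"on"` or `"off"`.
#' @param unitSystem `"molecules"` or `"nM"`.
#' @return named numeric vector over the 8 species.
#' @examples
#' referenceState("on", "nM")[["C"]]   # 5.2 nM free Cdc20
#' @export
referenceState <- function(branch = c("on", "off"),
                        unitSystem = c("molecules", "nM")) {
  branch <- match.arg(branch)
  unitSystem <- match.arg(unitSystem)
  x <- if (branch == "on") .ON_MOL else .OFF_MOL
  if (unitSystem == "nM") x <- x / MOL_PER_NM
  x
}

#' Conserved moiety totals of a state
#'
#' APC total = A + AC + ACMC; Mad total = Mada + Madi + MC + ACMC; the
#' Cdc20 moiety total C + MC + AC + 2*ACMC counts the APC/C-MCC complex
#' twice (one Cdc20 bound to APC/C, one inside the MCC).
#'
#' @param state named numeric state vector (8 species, any unit system).
#' @return named numeric: `APC`, `Mad`, `Cdc20`.
#' @export
moietyTotals <- function(state) {
  c(APC = unname(state["A"] + state["AC"] + state["ACMC"]),
    Mad = unname(state["Mada"] + state["Madi"] + state["MC"] + state["ACMC"]),
    Cdc20 = unname(state["C"] + state["MC"] + state["AC"] +
                   2 * state["ACMC"]))
}

#' Saturating checkpoint signal of unattached kinetochores
#'
#' The dimensionless signal s(nUK) = kprime * nUK / (Jn + nUK) through
#' which unattached (or tension-less) kinetochores drive Mad activation;
#' monotone increasing and saturating at `kprime`.
#'
#' @param nUK number of unattached kinetochores (>= 0; fractional values
#'   are allowed, nUK being the continuous bifurcation parameter).
#' @param params a [CheckpointParams-class] object.
#' @return signal value(s).
#' @examples
#' checkpointSignal(10, checkpointParams())  # 163.46
#' @export
checkpointSignal <- function(nUK, params = checkpointParams()) {
  if (any(nUK < 0)) stop("nUK must be nonnegative")
  v <- params@values
  unname(v["kprime"] * nUK / (v["Jn"] + nUK))
}

#' The reaction network
#'
#' @return a [ReactionNetwork-class] with the 22 reactions, their
#'   stoichiometry over the extended state, and rate-law tags.
#' @export
reactionNetwork <- function() {
  rx <- list(
    ## name, rate-law tag, stoichiometry changes
    list("Cdc20 promoter activation",  "promoter",      c(ponCDC20 = 1)),
    list("Cdc20 promoter inactivation","promoter",      c(ponCDC20 = -1)),
    list("Cdc20 synthesis",            "synthesis",     c(C = 1)),
    list("Mps1 promoter activation",   "promoter",      c(ponX = 1)),
    list("Mps1 promoter inactivation", "promoter",      c(ponX = -1)),
    list("Mps1 synthesis",             "synthesis",     c(Mps1 = 1)),
    list("Cdc20 background degradation","mass_action",  c(C = -1)),
    list("Mps1 degradation",           "mass_action",   c(Mps1 = -1)),
    list("Mps1 background degradation","mass_action",   c(Mps1 = -1)),
    list("Mad activation",             "mad_activation",c(Madi = -1, Mada = 1)),
    list("Mad inactivation",           "mad_inactivation",
         c(Mada = -1, Madi = 1)),
    list("MCC formation",              "mass_action",   c(Mada = -1, C = -1, MC = 1)),
    list("MCC dissociation",           "mass_action",   c(MC = -1, Mada = 1, C = 1)),
    list("APC/C-Cdc20 formation",      "mass_action",   c(A = -1, C = -1, AC = 1)),
    list("APC/C-Cdc20 dissociation",   "mass_action",   c(AC = -1, A = 1, C = 1)),
    list("APC/C-MCC formation",        "mass_action",   c(MC = -1, AC = -1, ACMC = 1)),
    list("APC/C-MCC dissociation",     "mass_action",   c(ACMC = -1, MC = 1, AC = 1)),
    list("APC/C-MCC degradation",      "mass_action",
         c(ACMC = -1, A = 1, C = 1, Madi = 1)),
    list("MCC background degradation", "mass_action",   c(MC = -1, Madi = 1)),
    list("APC/C-Cdc20 background degradation", "mass_action",
         c(AC = -1, A = 1)),
    list("APC/C-MCC background degradation", "mass_action",
         c(ACMC = -1, A = 1, Madi = 1)),
    list("Kinetochore attachment",     "attachment",    c(nUK = -1)))
  S <- matrix(0L, nrow = length(.STATE_VARS), ncol = length(rx),
              dimnames = list(.STATE_VARS, vapply(rx, `[[`, "", 1L)))
  for (j in seq_along(rx)) {
    d <- rx[[j]][[3L]]
    S[names(d), j] <- as.integer(d)
  }
  new("ReactionNetwork", species = .STATE_VARS, stoich = S,
      rateLaw = vapply(rx, `[[`, "", 2L),
      reactions = vapply(rx, `[[`, "", 1L))
}

#' Reaction rates (propensities) at a state
#'
#' Evaluates all 22 rate laws. Bimolecular steps are mass action
#' (the association laws read APC/C-Cdc20 formation as kassAC * A * C and
#' MCC formation as kassMC * Mada * C); Mad activation is
#' kact * Mps1 * s(nUK) * Madi / (J + Madi) with the saturating
#' kinetochore signal s(); Mad inactivation is
#' kinact * Mada^2 / (J + Mada); synthesis is promoter-gated in the
#' stochastic system and direct in the deterministic mean field.
#'
#' @param state named numeric vector over the 8 species, optionally with
#'   `ponCDC20`, `ponX` and `nUK` entries (promoters default to 1).
#' @param params a [CheckpointParams-class] object.
#' @param nUK unattached kinetochores; overrides any `nUK` entry of `state`.
#' @return named numeric vector of 22 nonnegative rates (events/min or
#'   concentration/min, matching the unit system).
#' @export
reactionRates <- function(state, params, nUK = NULL) {
  v <- params@values
  get0 <- function(nm, default = NA_real_)
    if (nm %in% names(state)) unname(state[nm]) else default
  if (any(state[intersect(names(state), .STATE_VARS)] < -1e-12))
    stop("state components must be nonnegative")
  ponC <- get0("ponCDC20", 1)
  ponX <- get0("ponX", 1)
  if (is.null(nUK)) nUK <- get0("nUK", 0)
  s <- checkpointSignal(nUK, params)
  kdiss <- derivedRates(params)
  C <- get0("C"); A <- get0("A"); AC <- get0("AC"); Mada <- get0("Mada")
  Madi <- get0("Madi"); Mps1 <- get0("Mps1"); MC <- get0("MC")
  ACMC <- get0("ACMC")
  r <- c(
    v[["konCDC20"]] * (1 - ponC),
    v[["koffCDC20"]] * ponC,
    v[["ksynCDC20"]] * ponC,
    v[["konX"]] * (1 - ponX),
    v[["koffX"]] * ponX,
    v[["ksynX"]] * ponX,
    v[["kdegBG"]] * C,
    v[["kdegX"]] * Mps1 * AC,
    v[["kdegBGX"]] * Mps1,
    v[["kact"]] * Mps1 * s * Madi / (v[["J"]] + Madi),
    v[["kinact"]] * Mada^2 / (v[["J"]] + Mada),
    v[["kassMC"]] * Mada * C,
    kdiss[["kdissMC"]] * MC,
    v[["kassAC"]] * A * C,
    kdiss[["kdissAC"]] * AC,
    v[["kassACMC"]] * MC * AC,
    kdiss[["kdissACMC"]] * ACMC,
    v[["kdeg"]] * ACMC,
    v[["kdegBG"]] * MC,
    v[["kdegBG"]] * AC,
    v[["kdegBG"]] * ACMC,
    v[["katt"]] * nUK)
  names(r) <- reactionNetwork()@reactions
  r
}

#' Deterministic right-hand side
#'
#' Time derivative of the 8 molecular species with nUK held as an external
#' parameter. Promoter switching is ignored and synthesis enters at its
#' full rate (optionally scaled by the promoter duty cycle
#' kon/(kon+koff)); the attachment channel is excluded unless the caller
#' integrates nUK explicitly. Conservation of the APC and Mad moieties is
#' structural: the derivative is the stoichiometry matrix times the rate
#' vector.
#'
#' @param state named numeric vector over the 8 species.
#' @param params a [CheckpointParams-class] object.
#' @param nUK unattached kinetochores (external signal level).
#' @param dutyCycle multiplier on both synthesis rates (default 1; set to
#'   kon/(kon+koff) = 0.909 to use the bursting mean field).
#' @return named derivative vector over the 8 species.
#' @export
odeRHS <- function(state, params, nUK, dutyCycle = 1) {
  extra <- setdiff(names(state), .SPECIES)
  if (length(extra))
    stop("stochastic-only fields present in deterministic state: ",
         paste(extra, collapse = ", "))
  r <- reactionRates(state, params, nUK = nUK)
  r[c(1, 2, 4, 5, 22)] <- 0          # promoters and attachment are external
  r[c(3, 6)] <- r[c(3, 6)] * dutyCycle
  S <- reactionNetwork()@stoich[.SPECIES, ]
  drop(S %*% r)
}

#' Mutant specification constructor
#'
#' @param kassACFactor scale on the APC/C-Cdc20 association rate (e.g.
#'   0.65 for the APC-A mutant).
#' @param madTotalFactor scale on the conserved Mad pool (e.g. 1.25 for
#'   GAL1-MAD2).
#' @param mps1SynthesisFactor scale on Mps1 synthesis (e.g. 3 for the
#'   one-hour overexpression pulse).
#' @param window time window (min) of the Mps1 factor.
#' @return a [MutantSpec-class].
#' @export
mutantSpec <- function(kassACFactor = 1, madTotalFactor = 1,
                       mps1SynthesisFactor = 1, window = c(-Inf, Inf)) {
  new("MutantSpec", kassACFactor = kassACFactor,
      madTotalFactor = madTotalFactor,
      mps1SynthesisFactor = mps1SynthesisFactor, window = as.numeric(window))
}

#' Apply a mutant transform to a parameter set
#'
#' Scales the APC/C-Cdc20 association rate while holding the dissociation
#' rate fixed (the dissociation constant therefore moves inversely to the
#' factor: the mutation weakens binding, not the bound complex), and scales
#' Mps1 synthesis. The Mad-pool factor acts on initial conditions, not on
#' rate constants; see [mutantState()].
#'
#' @param params a [CheckpointParams-class].
#' @param spec a [MutantSpec-class].
#' @param time evaluation time for the windowed Mps1 factor (default:
#'   inside the window if the window is unbounded, otherwise 0).
#' @return transformed [CheckpointParams-class].
#' @export
applyMutant <- function(params, spec, time = 0) {
  v <- params@values
  f <- spec@kassACFactor
  v["kassAC"] <- v["kassAC"] * f
  v["kDAC"] <- v["kDAC"] / f          # kdissAC = kDAC * kassAC unchanged
  if (time >= spec@window[1] && time < spec@window[2])
    v["ksynX"] <- v["ksynX"] * spec@mps1SynthesisFactor
  new("CheckpointParams", values = v, unitSystem = params@unitSystem,
      acThreshold = params@acThreshold)
}

#' Apply a mutant transform to an initial state
#'
#' Adds the extra Mad of an overexpression mutant to the inactive pool, so
#' the conserved Mad moiety total scales by `madTotalFactor`.
#'
#' @param state named species vector.
#' @param spec a [MutantSpec-class].
#' @return transformed state.
#' @export
mutantState <- function(state, spec) {
  tot <- moietyTotals(state)[["Mad"]]
  state["Madi"] <- state["Madi"] + (spec@madTotalFactor - 1) * tot
  state
}

#' Read/write a parameter configuration file
#'
#' Flat key-value serialization (YAML or JSON by extension) using the
#' model's parameter names, plus `unit_system` and `ac_threshold`.
#'
#' @param params a [CheckpointParams-class].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `writeParamConfig` returns `path` invisibly; `readParamConfig`
#'   returns a [CheckpointParams-class].
#' @export
writeParamConfig <- function(params, path) {
  x <- c(as.list(params@values),
         list(unit_system = params@unitSystem,
              ac_threshold = params@acThreshold))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParamConfig
#' @param path file path.
#' @export
readParamConfig <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  us <- x$unit_system; thr <- x$ac_threshold
  x$unit_system <- NULL; x$ac_threshold <- NULL
  new("CheckpointParams", values = unlist(x), unitSystem = us,
      acThreshold = thr)
}
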