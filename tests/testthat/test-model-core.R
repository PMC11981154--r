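test_that("checkpoint signal is the saturating kinetochore function", {
  p <- checkpointParams()
  expect_identical(checkpointSignal(0, p), 0)
  expect_equal(checkpointSignal(0.4, p), 170 / 2)      # half saturation at Jn
  expect_equal(checkpointSignal(10, p), 170 * 10 / 10.4, tolerance = 1e-12)
  ## monotone and bounded by kprime
  u <- seq(0, 200, by = 0.5)
  s <- checkpointSignal(u, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s < 170))
  expect_error(checkpointSignal(-1, p), "nonnegative")
})

test_that("both parameter columns are stored side by side", {
  tab <- paramTable()
  expect_setequal(c("molecules", "nM_tabulated", "nM_volume_consistent"),
                  setdiff(names(tab), "parameter"))
  expect_equal(tab$molecules[tab$parameter == "kassAC"], 1.1e-1)
  expect_equal(tab$nM_tabulated[tab$parameter == "kassAC"], 4.4e-2)
  ## derived dissociation rates obey kdiss = KD * kass in both systems
  for (us in c("molecules", "nM")) {
    p <- checkpointParams(us)
    v <- paramValues(p)
    kd <- derivedRates(p)
    expect_equal(kd[["kdissMC"]], v[["kDMC"]] * v[["kassMC"]],
                 tolerance = 1e-12)
    expect_equal(kd[["kdissACMC"]], v[["kDACMC"]] * v[["kassACMC"]],
                 tolerance = 1e-12)
  }
})

test_that("the nM and molecule systems are the same model in two units", {
  ## 40 nM == 100 molecules; states convert by 2.5 and the vector field
  ## converts consistently, so the scaled derivatives agree
  d_mol <- odeRHS(referenceState("on", "molecules"),
                  checkpointParams("molecules"), 10)
  d_nM <- odeRHS(referenceState("on", "nM"), checkpointParams("nM"), 10)
  expect_equal(d_mol / 2.5, d_nM, tolerance = 1e-10)
})

test_that("reaction network conserves the APC and Mad moieties exactly", {
  net <- reactionNetwork()
  S <- net@stoich
  expect_identical(ncol(S), 22L)
  apc <- colSums(S[c("A", "AC", "ACMC"), ])
  mad <- colSums(S[c("Mada", "Madi", "MC", "ACMC"), ])
  expect_true(all(apc == 0))
  expect_true(all(mad == 0))
  ## Cdc20 moiety (ACMC counts twice) changes only via synthesis and
  ## degradation reactions
  cdc20 <- colSums(S[c("C", "MC", "AC"), ]) + 2 * S["ACMC", ]
  changing <- which(cdc20 != 0)
  expect_setequal(net@reactions[changing],
                  c("Cdc20 synthesis", "Cdc20 background degradation",
                    "APC/C-MCC degradation", "MCC background degradation",
                    "APC/C-Cdc20 background degradation",
                    "APC/C-MCC background degradation"))
  expect_equal(unname(cdc20[net@reactions == "APC/C-MCC background degradation"]),
               -2)
})

test_that("moiety totals of the reference states match the tabulated totals", {
  ## component sums agree with the tabulated conserved totals up to the
  ## table's rounding (one molecule / 0.4 nM)
  expect_equal(unname(moietyTotals(referenceState("on", "molecules"))),
               c(100, 175, 100), tolerance = 0.011)
  expect_equal(unname(moietyTotals(referenceState("off", "molecules"))),
               c(100, 175, 555), tolerance = 0.011)
  expect_equal(unname(moietyTotals(referenceState("on", "nM"))),
               c(40, 70, 40), tolerance = 0.011)
  expect_equal(unname(moietyTotals(referenceState("off", "nM"))[["Cdc20"]]),
               222, tolerance = 0.011)
})

test_that("reaction rates reproduce hand-computed fluxes at the ON state", {
  p <- checkpointParams("molecules")
  st <- c(referenceState("on", "molecules"), nUK = 10)
  r <- reactionRates(st, p)
  expect_length(r, 22L)
  expect_true(all(r >= 0))
  expect_equal(r[["APC/C-MCC degradation"]], 1.3 * 29)        # 37.7
  expect_equal(r[["Mps1 degradation"]], 2.4e-2 * 17 * 25)     # 10.2
  ## empty system: only promoter switching can fire
  r0 <- reactionRates(c(zeroState(), ponCDC20 = 1, ponX = 0, nUK = 0),
                      reducedParams(konCDC20 = 1, koffCDC20 = 0.1,
                                    konX = 1, koffX = 0.1))
  firing <- names(r0)[r0 > 0]
  expect_true(all(grepl("promoter", firing)))
})

test_that("Cdc20 synthesis balances total degradation at the arrest state", {
  p <- checkpointParams("molecules")
  st <- c(referenceState("on", "molecules"), nUK = 10)
  r <- reactionRates(st, p)
  synth <- paramValues(p)[["ksynCDC20"]] * (1 / 1.1)   # duty-weighted
  deg <- r[["Cdc20 background degradation"]] +
    r[["APC/C-MCC degradation"]] + r[["MCC background degradation"]] +
    r[["APC/C-Cdc20 background degradation"]] +
    2 * r[["APC/C-MCC background degradation"]]
  expect_lt(abs(synth - deg) / deg, 0.15)
})

test_that("ODE right-hand side conserves moieties and sits near the tabulated state", {
  p <- checkpointParams("molecules")
  ## conservation identities hold for arbitrary states
  set.seed(1)
  for (i in 1:20) {
    x <- stats::setNames(runif(8, 0, 200), speciesNames())
    d <- odeRHS(x, p, runif(1, 0, 12))
    expect_equal(d[["A"]] + d[["AC"]] + d[["ACMC"]], 0, tolerance = 1e-10)
    expect_equal(d[["Mada"]] + d[["Madi"]] + d[["MC"]] + d[["ACMC"]], 0,
                 tolerance = 1e-10)
  }
  ## the tabulated arrest state is a near-fixed point (the residual reflects
  ## the table's two-digit rounding)
  d <- odeRHS(referenceState("on", "molecules"), p, 10)
  r <- reactionRates(c(referenceState("on", "molecules"), nUK = 10), p)
  expect_lt(sqrt(sum(d^2)), 0.2 * max(r))
  expect_error(odeRHS(c(referenceState("on"), ponCDC20 = 1), p, 10),
               "stochastic-only")
})

test_that("mutant transforms scale the intended constants", {
  p <- checkpointParams("molecules")
  expect_equal(paramValues(applyMutant(p, mutantSpec())),
               paramValues(p))                        # identity
  pa <- applyMutant(p, mutantSpec(kassACFactor = 0.65))
  expect_equal(paramValues(pa)[["kassAC"]], 0.65 * 1.1e-1)
  ## dissociation rate fixed => KD rises as the factor falls
  expect_equal(derivedRates(pa)[["kdissAC"]], derivedRates(p)[["kdissAC"]])
  expect_equal(paramValues(pa)[["kDAC"]], 8.5 / 0.65)
  ## Mad pool: 1.25x of the 70 nM total = 87.5 nM, extra Mad inactive
  stG <- mutantState(referenceState("on", "nM"), mutantSpec(madTotalFactor = 1.25))
  expect_equal(moietyTotals(stG)[["Mad"]], 87.5)
  expect_equal(stG[["Mada"]], referenceState("on", "nM")[["Mada"]])
  ## windowed Mps1 overexpression
  pp <- mutantSpec(mps1SynthesisFactor = 3, window = c(0, 60))
  expect_equal(paramValues(applyMutant(p, pp, time = 30))[["ksynX"]], 33)
  expect_equal(paramValues(applyMutant(p, pp, time = 90))[["ksynX"]], 11)
  expect_error(mutantSpec(kassACFactor = -1), "positive")
  expect_error(mutantSpec(window = c(10, 5)), "start < end")
})

test_that("parameter configs round-trip through YAML and JSON", {
  p <- checkpointParams("nM")
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("pars.", ext))
    writeParamConfig(p, f)
    q <- readParamConfig(f)
    expect_equal(paramValues(q), paramValues(p))
    expect_identical(unitSystem(q), "nM")
    expect_equal(acThreshold(q), 32)
    unlink(f)
  }
})
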