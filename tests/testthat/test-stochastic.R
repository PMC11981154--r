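test_that("a dead network is constant and terminates cleanly", {
  pr <- protocolSpec("arrest", nUK0 = 5, tMax = 50, seed = 1L,
                     init = stats::setNames(c(3, 1, 4, 1, 5, 9, 2, 6),
                                            speciesNames()))
  tr <- ssaRun(pr, reducedParams(), recordDt = 10)
  expect_true(all(apply(tr@states, 2, function(x) length(unique(x)) == 1)))
  expect_true(is.na(tr@metadata$tCross))
})

test_that("runs are integer-valued, conserve moieties, and replay by seed", {
  pr <- protocolSpec("washout", seed = 5L, tMax = 300)
  tr <- ssaRun(pr, recordDt = 1)
  st <- tr@states
  expect_true(all(st == round(st)))
  expect_true(all(st >= 0))
  tot <- t(apply(st[, speciesNames()], 1, moietyTotals))
  expect_true(all(tot[, "APC"] == tot[1, "APC"]))  # integer-exact
  expect_true(all(tot[, "Mad"] == tot[1, "Mad"]))
  expect_true(all(diff(st[, "nUK"]) <= 0))    # attachment only removes
  tr2 <- ssaRun(pr, recordDt = 1)
  expect_identical(tr@states, tr2@states)     # bit-identical replay
  expect_identical(tr@metadata$tCross, tr2@metadata$tCross)
})

test_that("sequential attachment times match the closed-form mean", {
  ## katt-only process from nUK0 = 10: E[T] = (1/katt) * H_10
  pk <- reducedParams(katt = 0.03)
  ta <- vapply(1:150, function(s)
    ssaRun(protocolSpec("washout", seed = s, tMax = 5000), pk,
           recordDt = 0)@metadata$tAllAttached, 0)
  theory <- sum(1 / (1:10)) / 0.03          # 97.6 min
  expect_equal(mean(ta), theory, tolerance = 0.08)
})

test_that("SSA matches the bursty birth-death stationary law", {
  ## synthesis + background degradation of free Cdc20 only:
  ## mean = ksyn * duty / kdegBG with duty = kon/(kon+koff) = 0.909
  pb <- reducedParams(ksynCDC20 = 42, kdegBG = 0.038,
                      konCDC20 = 1, koffCDC20 = 0.1, konX = 1, koffX = 0.1)
  pr <- protocolSpec("arrest", nUK0 = 0, tMax = 12000, seed = 11L,
                     init = zeroState())
  tr <- ssaRun(pr, pb, recordDt = 1)
  keep <- tr@time > 2000                     # past the relaxation transient
  m <- mean(tr@states[keep, "C"])
  expect_equal(m, 42 * (1 / 1.1) / 0.038, tolerance = 0.03)
  expect_equal(mean(tr@states[keep, "ponCDC20"]), 1 / 1.1, tolerance = 0.02)
})

test_that("outcome classification follows the first-crossing rules", {
  mk <- function(tCross, nuk, tAll = NA) {
    new("Trajectory", time = 0, states = matrix(0, 1, 11,
        dimnames = list(NULL, speciesNames(TRUE))), unitSystem = "molecules",
        metadata = list(tCross = tCross, nUKAtCross = nuk,
                        tAllAttached = tAll, seed = 1L))
  }
  expect_identical(classifyOutcome(mk(300, 3))@classification, "adapted")
  expect_identical(classifyOutcome(mk(300, 0, 250))@classification, "exited")
  expect_identical(classifyOutcome(mk(NA, 4))@classification, "arrested")
})

test_that("arrested cells escape spontaneously, the reverse transition never happens", {
  ## ON -> OFF at fixed nUK = 10 within the experimental horizon
  ens <- runEnsemble(protocolSpec("arrest", tMax = 700), n = 20, seed0 = 3L)
  expect_gt(outcomeFractions(ens)[["adapted"]], 0.8)
  ## OFF -> ON is never observed over comparable horizons
  prOFF <- protocolSpec("arrest", tMax = 700, init = "off")
  for (s in 1:10) {
    prOFF@seed <- s
    tr <- ssaRun(prOFF, recordDt = 5)
    expect_gt(min(tr@states[, "AC"]), 50)
  }
})

test_that("ensembles are deterministic given (seed0, n) and fractions sum to 1", {
  e1 <- runEnsemble(protocolSpec("washout", tMax = 400), n = 10, seed0 = 2L)
  e2 <- runEnsemble(protocolSpec("washout", tMax = 400), n = 10, seed0 = 2L)
  expect_identical(outcomes(e1), outcomes(e2))
  expect_equal(sum(outcomeFractions(e1)), 1)
  expect_identical(outcomes(e1)$seed, 2:11)
})

test_that("exponential rate recovery and the degenerate-sample flag", {
  set.seed(9)
  fake <- new("EnsembleSummary",
              outcomes = data.frame(seed = 1:100,
                                    tCross = rexp(100, 0.01),
                                    nUKAtCross = 1, tAllAttached = NA,
                                    classification = "adapted"),
              n = 100L, fractions = c(adapted = 1, exited = 0, arrested = 0),
              protocol = protocolSpec("arrest"), seed0 = 1L)
  fit <- adaptationTimeDistribution(fake)
  expect_equal(fit$rate, 0.01, tolerance = 0.2)
  expect_true(fit$exponentialLike)
  fake@outcomes$tCross <- rep(100, 100)       # constant: CV 0, flagged
  fit0 <- adaptationTimeDistribution(fake)
  expect_equal(fit0$cv, 0)
  expect_false(fit0$exponentialLike)
  fake@outcomes <- fake@outcomes[1:5, ]
  expect_error(adaptationTimeDistribution(fake), "too few")
})

test_that("washout separates early adapters from checkpoint satisfiers", {
  ens <- runEnsemble(protocolSpec("washout"), n = 100, seed0 = 1L)
  av <- adaptersVsExiters(ens)
  expect_lt(av$R, 0)                 # earlier adapters carry more nUK
  expect_lt(av$wilcoxP, 0.05)        # adapters cross earlier
  ## empty-class flagging
  one <- ens
  one@outcomes <- one@outcomes[one@outcomes$classification == "adapted", ]
  expect_match(adaptersVsExiters(one)$flag, "exited")
})

test_that("checkpoint-strengthening interventions suppress adaptation", {
  base <- outcomeFractions(runEnsemble(protocolSpec("arrest", tMax = 400),
                                       n = 30, seed0 = 1L))[["adapted"]]
  apcA <- outcomeFractions(runEnsemble(
    protocolSpec("arrest", tMax = 400, mutant = mutantSpec(kassACFactor = 0.65)),
    n = 30, seed0 = 1L))[["adapted"]]
  gal <- outcomeFractions(runEnsemble(
    protocolSpec("arrest", tMax = 400, mutant = mutantSpec(madTotalFactor = 1.25)),
    n = 30, seed0 = 1L))[["adapted"]]
  expect_lt(apcA, base)
  expect_lt(gal, base)
})
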