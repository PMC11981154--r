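test_that("LoG localization index matches kernel arithmetic", {
  ## uniform image: index = value x kernel sum (near zero)
  ksum <- sum(analysisConfig()@logKernel)
  expect_equal(logLocalizationIndex(matrix(10, 9, 9)), 10 * ksum,
               tolerance = 1e-12)
  ## single bright pixel: center weight x intensity
  img <- matrix(0, 9, 9); img[5, 5] <- 7
  expect_equal(logLocalizationIndex(img), 0.0187 * 7, tolerance = 1e-12)
  expect_identical(logLocalizationIndex(matrix(0, 5, 5)), 0)
  expect_error(logLocalizationIndex(img, mask = matrix(FALSE, 9, 9)),
               "empty mask")
  ## translation invariance away from borders, linear in intensity
  img2 <- matrix(0, 11, 11); img2[4, 8] <- 7
  expect_equal(logLocalizationIndex(img2), logLocalizationIndex(img))
  expect_equal(logLocalizationIndex(3 * img), 3 * logLocalizationIndex(img))
})

test_that("Mad2 localization threshold is calibrated on the G1 window", {
  tt <- seq(0, 200, by = 10)
  flat <- cellTrace(tt, rep(100, 21), rep(2, 21))
  expect_false(any(mad2Localized(flat)))        # 110% of own max
  stepup <- cellTrace(tt, rep(100, 21), ifelse(tt > 30, 4, 2))
  loc <- mad2Localized(stepup)
  expect_identical(loc, tt > 30)
  expect_equal(mad2Threshold(stepup), 2.2)
  ## boundary convention is strict
  attick <- cellTrace(tt, rep(100, 21), ifelse(tt > 30, 2.2, 2))
  expect_false(any(mad2Localized(attick)))
  short <- cellTrace(c(30, 40), c(1, 1), c(1, 1))
  expect_error(mad2Localized(short), "calibration window")
})

test_that("kinetochore signal sums the 5x5 window on the raw projection", {
  img <- matrix(0, 15, 15); img[8, 8] <- 7
  expect_equal(as.numeric(kinetochoreSignal(img, c(8, 8))), 7)
  expect_equal(as.numeric(kinetochoreSignal(matrix(3, 15, 15), c(8, 8))),
               25 * 3)
  ## Gaussian spot: compare against a directly computed discrete sum
  a <- 50; sigma <- 1
  d2 <- outer((1:15 - 8)^2, (1:15 - 8)^2, `+`)
  spot <- a * exp(-d2 / (2 * sigma^2))
  oracle <- sum(spot[6:10, 6:10])
  expect_equal(as.numeric(kinetochoreSignal(spot, c(8, 8))), oracle)
  ## that sum captures ~96-98% of the full 2*pi*sigma^2*a mass
  expect_equal(oracle / (2 * pi * sigma^2 * a), 0.98, tolerance = 0.02)
  ## border clipping renormalizes and flags
  edge <- kinetochoreSignal(matrix(3, 15, 15), c(1, 1))
  expect_true(attr(edge, "clipped"))
  expect_equal(as.numeric(edge), 25 * 3)
  expect_error(kinetochoreSignal(img, c(0, 5)), "outside image")
})

test_that("degradation onset detection is exact on clean traces", {
  expect_equal(clb2DegradationTime(pieceTrace(tFall = 400)), 400)
  expect_true(is.na(clb2DegradationTime(pieceTrace(tFall = Inf))))
  rising <- cellTrace(seq(0, 300, 10), seq(10, 310, 10),
                      rep(1, 31), buddingTime = 20)
  expect_true(is.na(clb2DegradationTime(rising)))
  ## slow (partial-type) fall is still located
  expect_equal(clb2DegradationTime(pieceTrace(tFall = 300, rate = 0.005)),
               300)
  tiny <- cellTrace(c(0, 10, 20), c(1, 2, 3), c(1, 1, 1))
  expect_error(clb2DegradationTime(tiny), "smoothing window")
})

test_that("degradation onset is within one frame in >= 95% of noisy traces", {
  hits <- vapply(1:200, function(s) {
    tr <- pieceTrace(tFall = 400, noiseSd = 2, seed = s)
    td <- clb2DegradationTime(tr)
    !is.na(td) && abs(td - 400) <= 10
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the rate estimator is unbiased on exponentials and sign-correct", {
  for (rate in c(0.005, 0.02, 0.05, 0.1, 0.2)) {
    tr <- pieceTrace(tFall = 200, rate = rate, tEnd = 600)
    expect_equal(as.numeric(clb2DegradationRate(tr, 200)), rate,
                 tolerance = 1e-6)
  }
  flat <- cellTrace(seq(0, 300, 10), rep(50, 31), rep(1, 31))
  expect_equal(as.numeric(clb2DegradationRate(flat, 100)), 0,
               tolerance = 1e-12)
  rising <- cellTrace(seq(0, 300, 10), exp(0.02 * seq(0, 300, 10)),
                      rep(1, 31))
  expect_lt(as.numeric(clb2DegradationRate(rising, 100)), 0)
  ## nonpositive signals are shifted and flagged
  neg <- cellTrace(seq(0, 300, 10), c(rep(10, 16), seq(2, -26, by = -2)),
                   rep(1, 31))
  r <- clb2DegradationRate(neg, 160)
  expect_true(attr(r, "shifted"))
})

test_that("Clb2 behavior classes follow the partial-degradation rules", {
  expect_identical(as.character(classifyClb2Behavior(pieceTrace(Inf))),
                   "arrested")
  slow <- classifyClb2Behavior(pieceTrace(tFall = 300, rate = 0.005,
                                          tEnd = 800))
  expect_identical(as.character(slow), "partial")   # rate below 0.01
  full <- classifyClb2Behavior(pieceTrace(tFall = 300, rate = 0.05))
  expect_identical(as.character(full), "full")
  expect_equal(attr(full, "tDeg"), 300)
  expect_equal(attr(full, "rate"), 0.05, tolerance = 1e-6)
})

test_that("adaptation scoring joins Mad2 state at the degradation onset", {
  tt <- seq(0, 700, 10)
  mk <- function(deloc) {
    mad2 <- ifelse(tt <= 20, 1, ifelse(tt <= deloc, 3, 1))
    ct <- pieceTrace(tFall = 400)
    cellTrace(tt, ct@clb2, mad2, buddingTime = 20)
  }
  expect_identical(classifyAdaptation(mk(430)), "adapted")
  expect_identical(classifyAdaptation(mk(370)), "exited")
  partial <- pieceTrace(tFall = 300, rate = 0.005, tEnd = 800,
                        mad2 = rep(3, 81))
  expect_identical(classifyAdaptation(partial), "not-applicable")
})

test_that("missegregation predictor evaluates the independence model", {
  expect_identical(missegregationProbability(0, 16), 0)
  expect_identical(missegregationProbability(1, 7), 1)
  expect_equal(missegregationProbability(0.075, 16), 0.7127, tolerance = 1e-3)
  expect_error(missegregationProbability(1.2, 16), "\\[0, 1\\]")
  expect_error(missegregationProbability(0.5, 0), ">= 1")
})
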