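## Shared helpers for building reduced parameter sets and small fixtures.

## a molecule-unit parameter set with every rate zeroed except those named
reducedParams <- function(..., acThreshold = 1e9) {
  keep <- c(...)
  v <- paramValues(checkpointParams("molecules"))
  v[] <- 0
  v[names(keep)] <- keep
  v[c("Jn", "J")] <- c(0.4, 2.1)        # saturation constants stay positive
  new("CheckpointParams", values = v, unitSystem = "molecules",
      acThreshold = acThreshold)
}

zeroState <- function() stats::setNames(rep(0, 8), speciesNames())

## noise-free rise-plateau-fall trace on a 10-min grid
pieceTrace <- function(tFall = 400, rate = 0.05, tEnd = 700, plateau = 100,
                       noiseSd = 0, seed = 1L, mad2 = NULL) {
  tt <- seq(0, tEnd, by = 10)
  rise <- pmin(pmax((tt - 20) / 40, 0), 1)
  clb2 <- plateau * rise
  if (is.finite(tFall)) {
    post <- tt > tFall
    clb2[post] <- plateau * exp(-rate * (tt[post] - tFall))
  }
  if (noiseSd > 0) {
    set.seed(seed)
    clb2 <- clb2 + rnorm(length(tt), 0, noiseSd)
  }
  if (is.null(mad2)) mad2 <- rep(1, length(tt))
  cellTrace(tt, clb2, mad2, buddingTime = 20)
}
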